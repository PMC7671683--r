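test_that("a column is called iff the foreground is uniform and its residue is outgroup-absent", {
  cfg <- toy_panel()
  # foreground {L, L}, outgroup {P x 9}: one call
  m <- one_column_msa(c("L", "L"), rep("P", 9))
  calls <- detect_substitutions(m, cfg)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$foreground_residue, "L")
  expect_equal(calls$column, 1L)
  expect_equal(outgroup_residue_vector(calls$outgroup_residues), rep("P", 9))
  expect_equal(calls$foreground_positions, "f1:1;f2:1")

  # foreground not uniform: no call
  expect_equal(nrow(detect_substitutions(
    one_column_msa(c("L", "M"), rep("P", 9)), cfg)), 0L)

  # residue present in one outgroup species: no call
  expect_equal(nrow(detect_substitutions(
    one_column_msa(c("L", "L"), c(rep("P", 8), "L")), cfg)), 0L)
})

test_that("ambiguity letters block foreground calls and are uninformative in the outgroup", {
  cfg <- toy_panel()
  # X in the foreground blocks the column
  expect_equal(nrow(detect_substitutions(
    one_column_msa(c("X", "X"), rep("P", 9)), cfg)), 0L)
  # X in the outgroup is dropped from the informative set
  m <- one_column_msa(c("L", "L"), c(rep("P", 4), rep("X", 5)))
  expect_equal(nrow(detect_substitutions(m, cfg, min_outgroup = 5)), 0L)
  calls <- detect_substitutions(m, cfg, min_outgroup = 4)
  expect_equal(calls$n_outgroup, 4L)
  expect_equal(outgroup_residue_vector(calls$outgroup_residues), rep("P", 4))
})

test_that("calls carry per-foreground-species precursor positions across gaps", {
  cfg <- toy_panel()
  rows <- c(f1 = "-MAL", f2 = "KMAL",
            stats::setNames(rep("KMAP", 9), paste0("o", 1:9)))
  calls <- detect_substitutions(msa(rows, gene_symbol = "G"), cfg)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$column, 4L)
  expect_equal(calls$foreground_positions, "f1:3;f2:4")
})

test_that("indel events are maximal same-kind column runs", {
  cfg <- toy_panel()
  og <- function(s) stats::setNames(rep(s, 9), paste0("o", 1:9))
  # columns 5-6 foreground-gapped with residue-bearing outgroup; column 7
  # has a gapped outgroup species, interrupting the run
  rows <- c(f1 = "AAAA--AA", f2 = "AAAA--AA", og("AAAAAAAA"))
  rows[["o3"]] <- "AAAAAA-A"
  ev <- detect_indels(msa(rows, gene_symbol = "G"), cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$column_start, 5L)
  expect_equal(ev$column_end, 6L)
  expect_equal(ev$kind, "foreground-deletion")

  # gap/residue/gap in the foreground: two length-1 events
  rows2 <- c(f1 = "A-A-A", f2 = "A-A-A", og("AAAAA"))
  ev2 <- detect_indels(msa(rows2, gene_symbol = "G"), cfg)
  expect_equal(nrow(ev2), 2L)
  expect_equal(ev2$length, c(1L, 1L))

  # outgroup-gapped columns with residue-bearing foreground: insertion
  rows3 <- c(f1 = "AAAAA", f2 = "AAAAA", og("AA--A"))
  ev3 <- detect_indels(msa(rows3, gene_symbol = "G"), cfg)
  expect_equal(ev3$kind, "foreground-insertion")
  expect_equal(c(ev3$column_start, ev3$column_end), c(3L, 4L))

  # a column gapped in one outgroup species is not foreground-specific
  rows4 <- c(f1 = "A-A", f2 = "A-A", og("AAA"))
  rows4[["o5"]] <- "A-A"
  expect_equal(nrow(detect_indels(msa(rows4, gene_symbol = "G"), cfg)), 0L)
})

test_that("detection is invariant to row order", {
  f <- simulate_family(sim_config(n_columns = 120, p_missing_species = 0,
                                  p_ambiguous = 0, seed = 9), 1)
  m <- f$msa
  calls <- detect_substitutions(m, f$family$config)
  ind <- detect_indels(m, f$family$config)
  perm <- msa(m$rows[rev(seq_along(m$rows))], gene_symbol = m$gene_symbol)
  expect_equal(detect_substitutions(perm, f$family$config), calls)
  expect_equal(detect_indels(perm, f$family$config), ind)
})

test_that("substitution calls never overlap indel ranges", {
  cfg <- sim_config(n_families = 8, n_columns = 150, n_planted_indels = 2,
                    n_planted_substitutions = 2, p_missing_species = 0,
                    p_ambiguous = 0, seed = 13)
  d <- simulate_dataset(cfg)
  for (f in d$families) {
    calls <- detect_substitutions(f$msa, f$family$config)
    ind <- detect_indels(f$msa, f$family$config)
    for (k in seq_len(nrow(ind))) {
      expect_false(any(calls$column >= ind$column_start[[k]] &
                       calls$column <= ind$column_end[[k]]))
    }
  }
})

test_that("near-miss sites appear only in the partial diagnostic listing", {
  cfg <- toy_panel()
  m <- one_column_msa(c("L", "P"), rep("P", 9))
  expect_equal(nrow(detect_substitutions(m, cfg)), 0L)
  part <- detect_partial_sites(m, cfg)
  expect_equal(nrow(part), 1L)
  expect_equal(part$species, "f1")
  expect_equal(part$residue, "L")
})

test_that("detection errors when a foreground species is absent", {
  cfg <- toy_panel()
  rows <- c(f1 = "LLL", stats::setNames(rep("PPP", 9), paste0("o", 1:9)))
  expect_error(detect_substitutions(msa(rows, gene_symbol = "G"), cfg),
               "foreground species missing")
  expect_error(detect_indels(msa(rows, gene_symbol = "G"), cfg),
               "foreground species missing")
})
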