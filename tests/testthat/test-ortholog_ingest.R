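test_that("parse_family_fasta reads the pipe-separated header dialect", {
  path <- write_fasta_text(c(
    ">ags|XP001|ATP5G1", "MASTRVL",
    ">hsa|NP005166|ATP5G1", "MASTRVLA"
  ))
  rec <- parse_family_fasta(path)
  expect_equal(rec$species_id, c("ags", "hsa"))
  expect_equal(rec$accession, c("XP001", "NP005166"))
  expect_equal(rec$sequence, c("MASTRVL", "MASTRVLA"))

  cfg <- ground_squirrel_panel()
  rec2 <- parse_family_fasta(path, cfg)
  expect_equal(rec2$source, c("foreground-db", "reference-db"))
})

test_that("parse_family_fasta tags off-panel species and warns", {
  path <- write_fasta_text(c(">zzz|A1|G1", "MKV", ">ags|A2|G1", "MKV"))
  expect_warning(rec <- parse_family_fasta(path, ground_squirrel_panel()),
                 "unknown")
  expect_equal(rec$source[rec$species_id == "zzz"], "unknown")
  expect_equal(nrow(rec), 2L)
})

test_that("parse_family_fasta rejects malformed entries", {
  expect_error(parse_family_fasta(write_fasta_text(
    c(">ags|A1|G1", "MKV", ">hsa|A2|G1"))), "empty sequence")
  expect_error(parse_family_fasta(write_fasta_text(
    c(">ags_noaccession", "MKV"))), "entry 1")
  expect_error(parse_family_fasta(write_fasta_text(
    c(">ags|A1|G1", "MK-V"))), "ungapped")
  expect_error(parse_family_fasta(tempfile()), "not found")
})

test_that("filter_by_alias keeps accepted aliases case-insensitively", {
  records <- rbind(rec("ags", "A1", "MKV", gene = "ATP5G1"),
                   rec("hsa", "A2", "MKV", gene = "atp5mc1 "),
                   rec("mmu", "A3", "MKV", gene = "ATP5G2"))
  aliases <- list(ATP5G1 = c("ATP5G1", "ATP5MC1", "Su9"))
  expect_message(kept <- filter_by_alias(records, "ATP5G1", aliases),
                 "dropped 1")
  expect_equal(kept$accession, c("A1", "A2"))

  # empty alias set: declared fallback keeps everything with a warning
  expect_warning(all_kept <- filter_by_alias(records, "ATP5G1", list()),
                 "keeping all")
  expect_equal(nrow(all_kept), 3L)
})

test_that("percent_identity matches a brute-force global alignment oracle", {
  expect_identical(percent_identity("MASTRVL", "MASTRVL"), 1)
  # toy pair: best alignment introduces no gaps, 5 matches over 6 columns
  expect_equal(nw_identity_oracle("ACDEFG", "ACDEFA"), 5 / 6)
  expect_equal(percent_identity("ACDEFG", "ACDEFA"), 5 / 6, tolerance = 1e-12)
  # a pair whose optimum requires one gap
  expect_equal(percent_identity("MKVWW", "MKVAWW"),
               nw_identity_oracle("MKVWW", "MKVAWW"), tolerance = 1e-12)
  expect_error(percent_identity("", "ACD"), "empty")
})

test_that("percent_identity is symmetric and reflexive", {
  set.seed(11)
  for (i in 1:12) {
    a <- paste(sample(cladesubs:::AA20, sample(5:30, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(cladesubs:::AA20, sample(5:30, 1), replace = TRUE),
               collapse = "")
    expect_identical(percent_identity(a, b), percent_identity(b, a))
    expect_identical(percent_identity(a, a), 1)
  }
})

test_that("resolve_species_records maximizes mean identity with content-based ties", {
  refs <- rec("hsa", "R1", "MASTRVLAAK")
  cands <- rbind(rec("bta", "C1", "MASTRVLAAK"),
                 rec("bta", "C2", "MASTR"))
  expect_equal(resolve_species_records(cands, refs)$accession, "C1")
  # single candidate passes through unchanged
  expect_equal(resolve_species_records(cands[1, ], refs)$accession, "C1")
  # equal identity and length: smallest accession wins
  tied <- rbind(rec("bta", "B2", "MASTRVLAAK"),
                rec("bta", "A1", "MASTRVLAAK"))
  expect_equal(resolve_species_records(tied, refs)$accession, "A1")
  # permutation invariance: tie-breaks are content-based
  expect_equal(resolve_species_records(tied[2:1, ], refs)$accession, "A1")
  expect_error(resolve_species_records(cands[0, ], refs), "empty candidate")
})

test_that("resolve_family assembles one record per species and relabels aliases", {
  cfg <- species_config(c("f1", "f2"), c("o1", "o2"), reference = "o1")
  records <- rbind(
    rec("f1", "A1", "MKVWLLARTS"),
    rec("f2", "B1", "MKVWLLARTS", gene = "ALIAS1"),
    rec("o1", "C1", "MKVWLLARTS"),
    rec("o1", "C2", "MKVW"),       # short second record, loses resolution
    rec("o2", "D1", "MKVWLLARTS"),
    rec("zz", "E1", "MKVWLLARTS") # off panel, dropped
  )
  fam <- suppressWarnings(suppressMessages(
    resolve_family(records, "G1", cfg,
                   aliases = list(G1 = c("G1", "ALIAS1")))))
  expect_s3_class(fam, "ortholog_family")
  expect_setequal(fam$records$species_id, c("f1", "f2", "o1", "o2"))
  expect_true(all(fam$records$gene_symbol == "G1"))
  expect_equal(fam$records$accession[fam$records$species_id == "o1"], "C1")
  expect_true(has_complete_foreground(fam))

  fam2 <- suppressWarnings(suppressMessages(
    resolve_family(records[records$species_id != "f1", ], "G1", cfg)))
  expect_false(has_complete_foreground(fam2))
})

test_that("decoy isoforms are never selected when the true record is present", {
  cfg <- sim_config(n_families = 6, n_columns = 80, p_missing_species = 0,
                    p_extra_isoform = 1, p_ambiguous = 0, seed = 5)
  for (i in 1:6) {
    f <- simulate_family(cfg, i)
    fam <- suppressWarnings(suppressMessages(
      resolve_family(f$candidates, f$family$gene_symbol, f$family$config)))
    expect_true(all(grepl("-1$", fam$records$accession)),
                info = paste("family", i))
  }
})
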