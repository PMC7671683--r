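test_that("column_distribution is the weighted, pseudocounted residue frequency", {
  w <- c(s1 = 0.25, s2 = 0.25, s3 = 0.5)
  d <- column_distribution(c(s1 = "A", s2 = "A", s3 = "A"), w, pseudocount = 0)
  expect_equal(unname(d$p["A"]), 1)
  expect_equal(sum(d$p), 1)

  d2 <- column_distribution(c(s1 = "A", s2 = "A", s3 = "C"), w, pseudocount = 0)
  expect_equal(unname(d2$p["A"]), 0.5)
  expect_equal(unname(d2$p["C"]), 0.5)

  # weights renormalize over the contributing set
  d3 <- column_distribution(c(s1 = "A", s3 = "C"), w, pseudocount = 0)
  expect_equal(unname(d3$p["A"]), 1 / 3)

  expect_error(column_distribution(c(s1 = "-", s2 = "-"), w, 0),
               "undefined distribution")
})

test_that("JSD closed forms hold", {
  q <- background_distribution("uniform")
  # identical distributions diverge by zero
  expect_equal(jsd_divergence(q, q), 0)
  bg <- background_distribution("blosum62")
  expect_equal(jsd_divergence(bg, bg), 0)

  # point mass vs uniform: frozen from the independent direct-summation
  # oracle (0.5*log2(1/0.525) + 0.5*(0.05*log2(0.05/0.525) + 0.95))
  p <- stats::setNames(c(1, rep(0, 19)), cladesubs:::AA20)
  expect_equal(jsd_oracle(p, q), 0.8549974005, tolerance = 1e-9)
  expect_equal(jsd_divergence(p, q), 0.8549974005, tolerance = 1e-6)

  # the linear gap penalty halves the score at gap_fraction 0.5
  s0 <- jsd_conservation(list(p = p, gap_fraction = 0), q)
  s5 <- jsd_conservation(list(p = p, gap_fraction = 0.5), q)
  expect_equal(s5, s0 / 2, tolerance = 1e-12)

  expect_error(jsd_divergence(c(1.1, -0.1, rep(0, 18)), q), "negative")
  expect_error(jsd_divergence(p * 2, q), "sum")
})

test_that("JSD equals the brute-force oracle and stays in [0, 1]", {
  set.seed(31)
  worst <- 0
  for (i in 1:400) {
    p <- random_distribution()
    q <- random_distribution()
    v <- jsd_divergence(p, q)
    worst <- max(worst, abs(v - jsd_oracle(p, q)))
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
  expect_lt(worst, 1e-10)
})

test_that("JSD is maximized by the point mass on the rarest background residue", {
  q <- background_distribution("blosum62")
  point <- function(a) {
    p <- stats::setNames(rep(0, 20), cladesubs:::AA20); p[[a]] <- 1; p
  }
  scores <- vapply(cladesubs:::AA20, function(a) jsd_divergence(point(a), q), 0)
  expect_equal(names(which.max(scores)), names(which.min(q)))
  set.seed(5)
  for (i in 1:50) {
    expect_lte(jsd_divergence(random_distribution(), q), max(scores))
  }
})

test_that("sharpening the column distribution never decreases JSD", {
  q <- background_distribution("blosum62")
  set.seed(8)
  for (i in 1:30) {
    p <- random_distribution()
    target <- stats::setNames(rep(0, 20), cladesubs:::AA20)
    target[[names(which.max(p))]] <- 1
    mix <- seq(0, 1, by = 0.25)
    vals <- vapply(mix, function(t)
      jsd_divergence((1 - t) * p + t * target, q), 0)
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("mean_outgroup_blosum averages canonical BLOSUM62 entries", {
  expect_equal(mean_outgroup_blosum("L", rep("P", 9)), -3)
  expect_equal(mean_outgroup_blosum("A", rep("A", 9)), 4)
  expect_equal(mean_outgroup_blosum("L", c(rep("P", 8), "M")),
               (8 * (-3) + 2) / 9)
  # invariant to outgroup ordering
  expect_equal(mean_outgroup_blosum("L", c("M", rep("P", 8))),
               mean_outgroup_blosum("L", c(rep("P", 8), "M")))
  expect_error(mean_outgroup_blosum("L", character(0)), "no informative")
  expect_error(mean_outgroup_blosum("L", c("P", "@")), "alphabet")
})

test_that("score_substitutions composes column distribution, JSD and BLOSUM62", {
  cfg <- toy_panel()
  m <- one_column_msa(c("L", "L"), rep("P", 9))
  w <- henikoff_weights(m)
  calls <- detect_substitutions(m, cfg)
  sc <- score_substitutions(m, calls, w, cfg)
  # outgroup column is all P: jsd equals the (pseudocounted) point-mass value
  q <- background_distribution("blosum62")
  p_point <- stats::setNames(rep(0, 20), cladesubs:::AA20); p_point[["P"]] <- 1
  expect_equal(sc$jsd, jsd_divergence(p_point, q), tolerance = 1e-4)
  expect_equal(sc$mean_blosum, -3)

  # maximally diverse outgroup column scores strictly below the point mass
  m2 <- one_column_msa(c("L", "L"),
                       c("A", "R", "N", "D", "C", "Q", "E", "G", "H"))
  sc2 <- score_substitutions(m2, detect_substitutions(m2, cfg),
                             henikoff_weights(m2), cfg)
  expect_lt(sc2$jsd, sc$jsd)

  # empty call set passes through
  empty <- detect_substitutions(one_column_msa(c("L", "M"), rep("P", 9)), cfg)
  sc3 <- score_substitutions(m, empty, w, cfg)
  expect_equal(nrow(sc3), 0L)
  expect_true(all(c("jsd", "mean_blosum") %in% names(sc3)))
})

test_that("conservation defaults to the outgroup-only column", {
  cfg <- toy_panel()
  m <- one_column_msa(c("L", "L"), rep("P", 9))
  w <- henikoff_weights(m)
  calls <- detect_substitutions(m, cfg)
  excl <- score_substitutions(m, calls, w, cfg)$jsd
  incl <- score_substitutions(
    m, calls, w, cfg,
    scoring_config(include_foreground_in_conservation = TRUE))$jsd
  # diluting the column with the divergent foreground residue lowers it
  expect_lt(incl, excl)
})

test_that("rank_and_flag flags exactly ceil(top_fraction * n) in composite-rank mode", {
  mk <- function(n, seed) {
    set.seed(seed)
    data.frame(gene_symbol = sprintf("G%03d", seq_len(n)),
               column = seq_len(n), position = seq_len(n),
               jsd = runif(n), mean_blosum = sample(-4:4, n, TRUE),
               stringsAsFactors = FALSE)
  }
  r200 <- rank_and_flag(mk(200, 1), scoring_config(top_fraction = 0.01))
  expect_equal(sum(r200$flagged), 2L)
  r50 <- rank_and_flag(mk(50, 2), scoring_config(top_fraction = 0.01))
  expect_equal(sum(r50$flagged), 1L)
  expect_error(rank_and_flag(mk(0, 3)), "empty")

  # flagged set is invariant to input order
  x <- mk(120, 4)
  rA <- rank_and_flag(x, scoring_config(top_fraction = 0.05))
  shuf <- x[sample(nrow(x)), ]
  rB <- rank_and_flag(shuf, scoring_config(top_fraction = 0.05))
  keyA <- sort(paste(rA$gene_symbol[rA$flagged], rA$column[rA$flagged]))
  keyB <- sort(paste(rB$gene_symbol[rB$flagged], rB$column[rB$flagged]))
  expect_identical(keyA, keyB)

  # with all composites equal, the declared tie-break chain decides
  tied <- data.frame(gene_symbol = c("B", "A", "C"), column = c(2L, 1L, 3L),
                     position = 1:3, jsd = 0.5, mean_blosum = 0,
                     stringsAsFactors = FALSE)
  rt <- rank_and_flag(tied, scoring_config(top_fraction = 0.01))
  expect_identical(rt$gene_symbol[rt$flagged], "A")
})

test_that("quadrant mode requires both a high JSD and a low BLOSUM62", {
  set.seed(6)
  n <- 100
  x <- data.frame(gene_symbol = sprintf("G%03d", 1:n), column = 1:n,
                  position = 1:n, jsd = runif(n),
                  mean_blosum = runif(n, -4, 4), stringsAsFactors = FALSE)
  r <- rank_and_flag(x, scoring_config(top_fraction = 0.1,
                                       flag_mode = "quadrant"))
  hi <- quantile(x$jsd, 0.9, names = FALSE)
  lo <- quantile(x$mean_blosum, 0.1, names = FALSE)
  expect_identical(r$flagged, x$jsd >= hi & x$mean_blosum <= lo)
})

test_that("percentiles are pooled fractions at-or-below", {
  x <- data.frame(gene_symbol = c("A", "B", "C", "D"), column = 1:4,
                  position = 1:4, jsd = c(0.1, 0.4, 0.4, 0.9),
                  mean_blosum = c(-3, 0, 2, 4), stringsAsFactors = FALSE)
  r <- rank_and_flag(x, scoring_config(top_fraction = 0.25))
  expect_equal(r$jsd_percentile, c(0.25, 0.75, 0.75, 1))
  expect_equal(r$blosum_percentile, c(0.25, 0.5, 0.75, 1))
  expect_equal(r$composite, (r$jsd_percentile + 1 - r$blosum_percentile) / 2)
})

test_that("substitution matrices load from NCBI-format files identically", {
  b62 <- load_substitution_matrix("BLOSUM62")
  path <- tempfile(fileext = ".txt")
  lines <- c("# canonical BLOSUM62, NCBI layout",
             paste(" ", paste(colnames(b62), collapse = " ")),
             vapply(rownames(b62), function(r)
               paste(r, paste(b62[r, ], collapse = " ")), ""))
  writeLines(lines, path)
  from_file <- load_substitution_matrix(path)
  expect_equal(from_file[rownames(b62), colnames(b62)], b62,
               ignore_attr = TRUE)
})
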