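# Background amino acid frequencies associated with the BLOSUM62 matrix
# (the conservation-scoring convention); normalized on use since the
# published values sum to 1.002.
BLOSUM62_BACKGROUND <- c(
  A = 0.078, R = 0.051, N = 0.041, D = 0.052, C = 0.024, Q = 0.034,
  E = 0.059, G = 0.083, H = 0.025, I = 0.062, L = 0.092, K = 0.056,
  M = 0.024, F = 0.044, P = 0.043, S = 0.059, T = 0.055, W = 0.014,
  Y = 0.034, V = 0.072
)

#' Scoring configuration
#'
#' Collects every tunable of the conservation / divergence scoring stage.
#'
#' @param lambda Mixture weight of the Jensen-Shannon divergence, in (0,1).
#' @param background `"blosum62"` (amino acid frequencies associated with
#'   the BLOSUM62 matrix; default), `"uniform"`, `"alignment"` (estimated
#'   from the alignment's residues), or a named 20-vector of frequencies.
#' @param pseudocount Additive mass per residue before normalizing a column
#'   distribution; keeps KL terms finite without distorting small panels.
#' @param window_radius Columns of sequence context averaged into the score
#'   (0 disables windowing).
#' @param window_weight Weight of the window mean when `window_radius > 0`.
#' @param matrix Substitution matrix: a name resolvable by
#'   [load_substitution_matrix()] (default `"BLOSUM62"`), a path to an
#'   NCBI-format matrix file, or a numeric matrix.
#' @param include_foreground_in_conservation If `FALSE` (default) the JSD
#'   column distribution is estimated from the outgroup only, so the score
#'   measures how conserved the site is among the species that do not carry
#'   the variant.
#' @param top_fraction Fraction of pooled substitutions to flag (default
#'   0.01, the "top 1%").
#' @param flag_mode `"composite-rank"` (default): flag the
#'   `ceil(top_fraction * n)` substitutions with the best combined
#'   percentile rank; `"quadrant"`: flag substitutions jointly above the
#'   JSD quantile and below the BLOSUM62 quantile.
#' @return A `scoring_config` object.
#' @export
scoring_config <- function(lambda = 0.5,
                           background = "blosum62",
                           pseudocount = 1e-7,
                           window_radius = 0L,
                           window_weight = 0.5,
                           matrix = "BLOSUM62",
                           include_foreground_in_conservation = FALSE,
                           top_fraction = 0.01,
                           flag_mode = c("composite-rank", "quadrant")) {
  stopifnot(lambda > 0, lambda < 1, pseudocount >= 0,
            window_radius >= 0, window_weight >= 0, window_weight <= 1,
            top_fraction > 0, top_fraction <= 1)
  structure(
    list(lambda = lambda, background = background, pseudocount = pseudocount,
         window_radius = as.integer(window_radius),
         window_weight = window_weight, matrix = matrix,
         include_foreground_in_conservation = include_foreground_in_conservation,
         top_fraction = top_fraction, flag_mode = match.arg(flag_mode)),
    class = "scoring_config"
  )
}

#' Resolve a background amino acid distribution
#'
#' @param background See [scoring_config()].
#' @param m Optional [msa()], required for `background = "alignment"`.
#' @return Named numeric 20-vector over [AA20] order, summing to 1.
#' @export
background_distribution <- function(background = "blosum62", m = NULL) {
  if (is.numeric(background)) {
    q <- background[AA20]
    if (anyNA(q)) stop("numeric background must name all 20 standard residues")
  } else if (identical(background, "blosum62")) {
    q <- BLOSUM62_BACKGROUND[AA20]
  } else if (identical(background, "uniform")) {
    q <- stats::setNames(rep(1 / 20, 20), AA20)
  } else if (identical(background, "alignment")) {
    if (is.null(m)) stop("alignment-derived background requires an msa")
    chars <- unlist(lapply(m$rows, split_chars), use.names = FALSE)
    counts <- table(factor(chars[chars %in% AA20], levels = AA20))
    if (sum(counts) == 0) stop("alignment contains no standard residues")
    q <- as.numeric(counts) + 1e-7
    names(q) <- AA20
  } else stop("unknown background: ", background)
  q / sum(q)
}

#' Load a substitution matrix
#'
#' Accepts a matrix name bundled with Biostrings (e.g. `"BLOSUM62"`), a path
#' to a standard NCBI-format matrix file, or a numeric matrix, and returns
#' the numeric matrix.
#'
#' @param matrix Name, path, or matrix.
#' @return Numeric substitution matrix with residue dimnames.
#' @export
load_substitution_matrix <- function(matrix = "BLOSUM62") {
  if (is.matrix(matrix)) return(matrix)
  if (file.exists(matrix)) {
    lines <- readLines(matrix)
    lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    alphabet <- strsplit(trimws(lines[[1L]]), "[[:space:]]+")[[1L]]
    body <- lapply(lines[-1L], function(l) strsplit(trimws(l), "[[:space:]]+")[[1L]])
    rown <- vapply(body, `[[`, "", 1L)
    vals <- t(vapply(body, function(x) as.numeric(x[-1L]),
                     numeric(length(alphabet))))
    dimnames(vals) <- list(rown, alphabet)
    return(vals)
  }
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' Weighted residue distribution of an alignment column
#'
#' @param residues Named character vector for one column (see
#'   [column_residues()]), restricted to the contributing species.
#' @param weights Sequence weights covering the contributing species;
#'   renormalized over exactly that set.
#' @param pseudocount Additive mass per residue before normalization.
#' @return List with `p` (named 20-vector over [AA20], sums to 1) and
#'   `gap_fraction` (weighted gap share among the contributing species).
#'   Ambiguity letters contribute neither residue mass nor gap mass.
#' @export
column_distribution <- function(residues, weights, pseudocount = 1e-7) {
  if (length(residues) == 0L) stop("column_distribution: no contributing species")
  if (!all(names(residues) %in% names(weights)))
    stop("column_distribution: weights do not cover the contributing species")
  w <- weights[names(residues)]
  w <- w / sum(w)
  informative <- is_standard_residue(residues)
  if (!any(informative))
    stop("undefined distribution: no informative residues in column")
  mass <- stats::setNames(rep(pseudocount, 20), AA20)
  for (i in which(informative)) {
    mass[[residues[[i]]]] <- mass[[residues[[i]]]] + w[[i]]
  }
  list(p = mass / sum(mass), gap_fraction = sum(w[residues == GAP]))
}

#' Jensen-Shannon divergence between two residue distributions, in bits
#'
#' With `r = lambda * p + (1 - lambda) * q`, returns
#' `lambda * KL(p || r) + (1 - lambda) * KL(q || r)` using log base 2 and
#' the convention `0 * log 0 = 0`. For `lambda = 0.5` the value is bounded
#' by 1 bit.
#'
#' @param p,q Non-negative vectors summing to 1 (within 1e-6) over the same
#'   support.
#' @param lambda Mixture weight in (0,1).
#' @return Divergence in bits.
#' @export
jsd_divergence <- function(p, q, lambda = 0.5) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (any(p < 0) || any(q < 0)) stop("invalid distribution: negative mass")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("invalid distribution: mass does not sum to 1")
  r <- lambda * p + (1 - lambda) * q
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log2(a[i] / r[i]))
  }
  lambda * kl(p) + (1 - lambda) * kl(q)
}

#' Gap-penalized JSD conservation score of a column
#'
#' The raw divergence of the column distribution from the background is
#' scaled by `(1 - gap_fraction)`, so heavily gapped columns cannot score as
#' conserved. With `window_radius > 0`, the reported score additionally
#' averages in the penalized raw scores of flanking columns.
#'
#' @param dist A column distribution from [column_distribution()].
#' @param q Background distribution (named 20-vector).
#' @param config [scoring_config()].
#' @param neighbor_scores Optional numeric vector of flanking columns'
#'   penalized scores (used when `window_radius > 0`).
#' @return Score in \[0, 1\] for `lambda = 0.5`.
#' @export
jsd_conservation <- function(dist, q, config = scoring_config(),
                             neighbor_scores = NULL) {
  raw <- jsd_divergence(dist$p, q, config$lambda)
  score <- (1 - dist$gap_fraction) * raw
  if (config$window_radius > 0L && length(neighbor_scores) > 0L) {
    score <- (1 - config$window_weight) * score +
      config$window_weight * mean(neighbor_scores)
  }
  score
}

#' Mean foreground-vs-outgroup substitution matrix score
#'
#' The arithmetic mean of `matrix[foreground_residue, o]` over the
#' informative outgroup residue multiset. Low (negative) values mark
#' chemically drastic replacements.
#'
#' @param foreground_residue Single standard residue letter.
#' @param outgroup_residues Character vector (multiset) of informative
#'   outgroup residues.
#' @param matrix Numeric substitution matrix (default BLOSUM62).
#' @return Mean matrix score.
#' @export
mean_outgroup_blosum <- function(foreground_residue, outgroup_residues,
                                 matrix = load_substitution_matrix("BLOSUM62")) {
  if (length(outgroup_residues) == 0L)
    stop("mean_outgroup_blosum: no informative outgroup residues")
  letters_used <- c(foreground_residue, outgroup_residues)
  if (!all(letters_used %in% rownames(matrix)))
    stop("residue not in matrix alphabet: ",
         paste(setdiff(letters_used, rownames(matrix)), collapse = ", "))
  mean(matrix[foreground_residue, outgroup_residues])
}

#' Score substitution calls with JSD conservation and mean BLOSUM62
#'
#' For each call, the column distribution is estimated from the outgroup
#' species only (default) or from all species
#' (`include_foreground_in_conservation = TRUE`), with weights renormalized
#' over the contributing set; the JSD conservation score and the mean
#' foreground-vs-outgroup matrix score are attached. Percentiles and flags
#' are left to [rank_and_flag()], which needs the pooled multi-gene set.
#'
#' @param m The [msa()] the calls were made from.
#' @param calls Data.frame from [detect_substitutions()].
#' @param weights Sequence weights from [henikoff_weights()].
#' @param species [species_config()] naming the foreground and outgroup.
#' @param config [scoring_config()].
#' @return `calls` with numeric columns `jsd` and `mean_blosum` appended.
#' @export
score_substitutions <- function(m, calls, weights, species,
                                config = scoring_config()) {
  smat <- load_substitution_matrix(config$matrix)
  q <- background_distribution(config$background, m)
  contributing <- if (config$include_foreground_in_conservation) names(m$rows)
                  else intersect(species$outgroup, names(m$rows))
  if (NROW(calls) == 0L) {
    calls$jsd <- numeric(0)
    calls$mean_blosum <- numeric(0)
    return(calls)
  }
  calls$jsd <- NA_real_
  calls$mean_blosum <- NA_real_
  for (i in seq_len(NROW(calls))) {
    j <- calls$column[[i]]
    res <- column_residues(m, j, contributing)
    dist <- column_distribution(res, weights, config$pseudocount)
    nb <- NULL
    if (config$window_radius > 0L) {
      cols <- setdiff(
        seq(max(1L, j - config$window_radius),
            min(m$length, j + config$window_radius)), j)
      nb <- vapply(cols, function(k) {
        d <- tryCatch(
          column_distribution(column_residues(m, k, contributing), weights,
                              config$pseudocount),
          error = function(e) NULL)
        if (is.null(d)) NA_real_
        else (1 - d$gap_fraction) * jsd_divergence(d$p, q, config$lambda)
      }, 0)
      nb <- nb[!is.na(nb)]
    }
    calls$jsd[[i]] <- jsd_conservation(dist, q, config, nb)
    calls$mean_blosum[[i]] <- mean_outgroup_blosum(
      calls$foreground_residue[[i]],
      outgroup_residue_vector(calls$outgroup_residues[[i]]), smat)
  }
  calls
}

#' Rank the pooled substitution set and flag the top fraction
#'
#' Percentile ranks are computed over the pooled, multi-gene dataset: the
#' JSD percentile of a substitution is the fraction of pooled JSD values
#' less than or equal to its own, and likewise for the BLOSUM62 score. In
#' `composite-rank` mode the composite is
#' `(jsd_percentile + (1 - blosum_percentile)) / 2` — high conservation and
#' low (drastic) substitution score both push it up — and exactly
#' `ceil(top_fraction * n)` substitutions are flagged, with ties broken by
#' higher JSD, then lower mean BLOSUM62, then gene symbol, then column. In
#' `quadrant` mode a substitution is flagged iff its JSD is at or above the
#' `1 - top_fraction` quantile and its mean BLOSUM62 at or below the
#' `top_fraction` quantile.
#'
#' @param scored Pooled data.frame from [score_substitutions()] (all genes).
#' @param config [scoring_config()].
#' @return `scored` with `jsd_percentile`, `blosum_percentile`, `composite`,
#'   `flagged` columns appended; row order is preserved.
#' @export
rank_and_flag <- function(scored, config = scoring_config()) {
  n <- NROW(scored)
  if (n == 0L) stop("rank_and_flag: empty pooled substitution set")
  scored$jsd_percentile <- vapply(scored$jsd,
                                  function(x) mean(scored$jsd <= x), 0)
  scored$blosum_percentile <- vapply(scored$mean_blosum,
                                     function(x) mean(scored$mean_blosum <= x), 0)
  scored$composite <- (scored$jsd_percentile + (1 - scored$blosum_percentile)) / 2
  if (config$flag_mode == "composite-rank") {
    k <- ceiling(config$top_fraction * n)
    ord <- order(-scored$composite, -scored$jsd, scored$mean_blosum,
                 scored$gene_symbol, scored$column)
    scored$flagged <- FALSE
    scored$flagged[ord[seq_len(k)]] <- TRUE
  } else {
    hi_jsd <- stats::quantile(scored$jsd, 1 - config$top_fraction,
                              names = FALSE, type = 7)
    lo_blo <- stats::quantile(scored$mean_blosum, config$top_fraction,
                              names = FALSE, type = 7)
    scored$flagged <- scored$jsd >= hi_jsd & scored$mean_blosum <= lo_blo
  }
  scored
}
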