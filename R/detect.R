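#' Call foreground-clade-unique substitutions
#'
#' A column is called iff (a) every foreground species shows the same
#' standard residue (no gap, no ambiguity letter); (b) that residue appears
#' in no informative outgroup species at the column; and (c) at least
#' `min_outgroup` outgroup species are informative there. Informative means
#' a standard residue: gaps and ambiguity letters (X, B, Z) in the outgroup
#' are dropped from the comparison, contributing neither a match nor a
#' mismatch.
#'
#' @param m An [msa()] containing every foreground species.
#' @param config [species_config()].
#' @param min_outgroup Minimum number of informative outgroup species for a
#'   column to be callable (default 5); guards against calls driven by
#'   missing data.
#' @return Data.frame with one row per call: `gene_symbol`, `column`
#'   (1-based alignment column), `foreground_residue`, `outgroup_residues`
#'   (informative residues as a comma-separated string, outgroup order),
#'   `n_outgroup`, `foreground_positions` (per-species 1-based precursor
#'   positions, encoded `"species:pos"` joined by `;`), and `position` (the
#'   first foreground species' precursor position, for convenience).
#' @export
detect_substitutions <- function(m, config, min_outgroup = 5L) {
  fg <- config$foreground
  og <- intersect(config$outgroup, names(m$rows))
  if (!all(fg %in% names(m$rows)))
    stop("foreground species missing from msa: ",
         paste(setdiff(fg, names(m$rows)), collapse = ", "),
         " (family should have been excluded upstream)")
  mat <- msa_matrix(m)
  calls <- vector("list", m$length)
  for (j in seq_len(m$length)) {
    fg_res <- mat[fg, j]
    if (length(unique(fg_res)) != 1L) next
    res <- fg_res[[1L]]
    if (!is_standard_residue(res)) next
    og_res <- mat[og, j]
    informative <- og_res[is_standard_residue(og_res)]
    if (length(informative) < min_outgroup) next
    if (res %in% informative) next
    pos <- vapply(fg, function(s) column_to_residue_number(m, s, j), 0)
    calls[[j]] <- data.frame(
      gene_symbol = m$gene_symbol,
      column = j,
      foreground_residue = res,
      outgroup_residues = paste(informative, collapse = ","),
      n_outgroup = length(informative),
      foreground_positions = paste(paste0(fg, ":", pos), collapse = ";"),
      position = pos[[1L]],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, calls)
  if (is.null(out)) out <- empty_substitution_frame()
  rownames(out) <- NULL
  out
}

#' @noRd
empty_substitution_frame <- function() {
  data.frame(gene_symbol = character(), column = integer(),
             foreground_residue = character(), outgroup_residues = character(),
             n_outgroup = integer(), foreground_positions = character(),
             position = integer(), stringsAsFactors = FALSE)
}

#' Split an `outgroup_residues` field back into a character vector
#' @param x Comma-separated residue string from [detect_substitutions()].
#' @return Character vector of single residues.
#' @export
outgroup_residue_vector <- function(x) {
  strsplit(x, ",", fixed = TRUE)[[1L]]
}

#' Call foreground-specific indel events
#'
#' A foreground-deletion column has every foreground species gapped and
#' every outgroup species residue-bearing; a foreground-insertion column the
#' reverse. Maximal runs of consecutive same-kind columns are reported as
#' single events.
#'
#' @inheritParams detect_substitutions
#' @return Data.frame with columns `gene_symbol`, `column_start`,
#'   `column_end` (1-based, inclusive), `length`, `kind`
#'   (`"foreground-deletion"` or `"foreground-insertion"`).
#' @export
detect_indels <- function(m, config) {
  fg <- config$foreground
  og <- intersect(config$outgroup, names(m$rows))
  if (!all(fg %in% names(m$rows)))
    stop("foreground species missing from msa: ",
         paste(setdiff(fg, names(m$rows)), collapse = ", "))
  mat <- msa_matrix(m)
  kind <- character(m$length)
  for (j in seq_len(m$length)) {
    fg_gap <- mat[fg, j] == GAP
    og_gap <- mat[og, j] == GAP
    kind[[j]] <-
      if (all(fg_gap) && length(og) > 0L && !any(og_gap)) "foreground-deletion"
      else if (length(og) > 0L && all(og_gap) && !any(fg_gap)) "foreground-insertion"
      else ""
  }
  runs <- rle(kind)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != ""
  out <- data.frame(
    gene_symbol = rep(m$gene_symbol, sum(keep)),
    column_start = starts[keep],
    column_end = ends[keep],
    length = runs$lengths[keep],
    kind = runs$values[keep],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Diagnostic listing of partial (near-miss) foreground sites
#'
#' Columns where at least one — but not every — foreground species carries a
#' standard residue that is absent from the informative outgroup. These
#' sites fail the clade-uniformity requirement and are never scored; the
#' listing exists so borderline sites are visible rather than silently
#' dropped.
#'
#' @inheritParams detect_substitutions
#' @return Data.frame with `gene_symbol`, `column`, `species`, `residue`.
#' @export
detect_partial_sites <- function(m, config, min_outgroup = 5L) {
  fg <- config$foreground
  og <- intersect(config$outgroup, names(m$rows))
  mat <- msa_matrix(m)
  rows <- list()
  for (j in seq_len(m$length)) {
    fg_res <- mat[intersect(fg, rownames(mat)), j, drop = FALSE][, 1L]
    if (length(unique(fg_res)) == 1L) next  # uniform: either a call or nothing
    og_res <- mat[og, j]
    informative <- og_res[is_standard_residue(og_res)]
    if (length(informative) < min_outgroup) next
    uniq <- fg_res[is_standard_residue(fg_res) & !(fg_res %in% informative)]
    for (s in names(uniq)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_symbol = m$gene_symbol, column = j, species = s,
        residue = uniq[[s]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_symbol = character(), column = integer(),
                      species = character(), residue = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
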