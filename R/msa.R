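#' Construct a validated multiple sequence alignment object
#'
#' @param rows Named character vector: species id -> gapped row (residues
#'   plus `-`). All rows must have identical length >= 1.
#' @param gene_symbol Gene label the alignment belongs to.
#' @return An `msa` object with fields `gene_symbol`, `rows`, `length`.
#' @export
msa <- function(rows, gene_symbol = "") {
  rows <- unlist(rows)
  if (length(rows) == 0L) stop("msa: no rows")
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("msa: rows must be named by species id")
  if (anyDuplicated(names(rows))) stop("msa: duplicated species ids")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("msa validation error: ragged rows (lengths ",
         paste(unique(widths), collapse = ", "), ")")
  if (widths[[1L]] < 1L) stop("msa validation error: zero-length alignment")
  structure(
    list(gene_symbol = gene_symbol, rows = rows, length = widths[[1L]]),
    class = "msa"
  )
}

#' @export
print.msa <- function(x, ...) {
  cat("msa '", x$gene_symbol, "': ", length(x$rows), " rows x ",
      x$length, " columns\n", sep = "")
  invisible(x)
}

#' Load an aligned FASTA and validate it against an ortholog family
#'
#' Every row's ungapped sequence must reproduce the family's resolved record
#' for that species, so alignment columns are guaranteed to be a coordinate
#' system over exactly the resolved records.
#'
#' @param path Aligned FASTA (header dialect `species|accession|gene`).
#' @param family An `ortholog_family` from [resolve_family()].
#' @return A validated [msa()].
#' @export
load_msa <- function(path, family) {
  seqs <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("malformed aligned FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  sp <- vapply(strsplit(names(seqs), "|", fixed = TRUE), `[[`, "", 1L)
  rows <- stats::setNames(as.character(seqs), trimws(sp))
  m <- msa(rows, gene_symbol = family$gene_symbol)
  fam_seq <- stats::setNames(family$records$sequence, family$records$species_id)
  extra <- setdiff(names(m$rows), names(fam_seq))
  if (length(extra))
    stop("msa consistency error: alignment rows for species absent from the ",
         "family: ", paste(extra, collapse = ", "))
  for (s in names(m$rows)) {
    if (gsub("-", "", m$rows[[s]], fixed = TRUE) != fam_seq[[s]])
      stop("msa consistency error: ungapped row for species '", s,
           "' does not match the family record")
  }
  m
}

#' Character matrix view of an alignment
#'
#' @param m An [msa()].
#' @return Character matrix, one row per species (rownames = species ids),
#'   one column per alignment column.
#' @export
msa_matrix <- function(m) {
  do.call(rbind, lapply(m$rows, split_chars))
}

#' Map an alignment column to a 1-based residue position in one species
#'
#' Substitutions are reported in precursor (unprocessed protein) residue
#' coordinates, e.g. "leucine-32"; this maps the shared alignment coordinate
#' system back to each species' own numbering.
#'
#' @param m An [msa()].
#' @param species Species id present in the alignment.
#' @param column 1-based alignment column.
#' @return 1-based position of that column's residue in the species'
#'   ungapped sequence. Requesting a gapped position is an error.
#' @export
column_to_residue_number <- function(m, species, column) {
  if (!species %in% names(m$rows)) stop("species '", species, "' not in msa")
  if (column < 1L || column > m$length)
    stop("column ", column, " outside alignment (1..", m$length, ")")
  chars <- split_chars(m$rows[[species]])
  if (chars[[column]] == GAP)
    stop("undefined position: species '", species, "' is gapped at column ",
         column)
  sum(chars[seq_len(column)] != GAP)
}

#' Henikoff position-based sequence weights
#'
#' Down-weights redundant, near-identical rows so column statistics are not
#' dominated by over-represented lineages. For row s, the raw weight is the
#' mean over alignment columns of 1 / (r_c * k_{c,a}), where r_c is the
#' number of distinct non-gap residue types in column c and k_{c,a} the
#' number of rows carrying residue a there. All-gap columns are skipped; a
#' row's gap positions contribute the neutral value 1/n. Weights are
#' normalized to sum to one.
#'
#' @param m An [msa()].
#' @return Named numeric vector of weights (sums to 1).
#' @export
henikoff_weights <- function(m) {
  mat <- msa_matrix(m)
  n <- nrow(mat)
  raw <- numeric(n)
  used <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    res <- col[col != GAP]
    if (length(res) == 0L) next
    used <- used + 1L
    counts <- table(res)
    r <- length(counts)
    contrib <- ifelse(col == GAP, 1 / n, 1 / (r * as.numeric(counts[col])))
    raw <- raw + contrib
  }
  if (used == 0L) stop("henikoff_weights: alignment is all gaps")
  raw <- raw / used
  w <- raw / sum(raw)
  stats::setNames(w, rownames(mat))
}

#' Residues of one alignment column
#'
#' @param m An [msa()].
#' @param column 1-based column index.
#' @param species Optional species subset (default: all rows).
#' @return Named character vector of single characters (residue or `-`).
#' @export
column_residues <- function(m, column, species = names(m$rows)) {
  if (column < 1L || column > m$length)
    stop("column ", column, " outside alignment (1..", m$length, ")")
  vapply(m$rows[species], function(r) substr(r, column, column), "")
}

#' Weighted gap fraction of a column
#'
#' @param residues Named character vector for one column (e.g. from
#'   [column_residues()]).
#' @param weights Named weight vector covering the column's species; it is
#'   renormalized over exactly those species.
#' @return Weighted fraction of `-` in \[0, 1\].
#' @export
gap_fraction <- function(residues, weights) {
  if (!all(names(residues) %in% names(weights)))
    stop("gap_fraction: weights do not cover the column's species")
  w <- weights[names(residues)]
  w <- w / sum(w)
  sum(w[residues == GAP])
}
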