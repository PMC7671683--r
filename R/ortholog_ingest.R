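#' Read per-gene candidate protein records from FASTA
#'
#' Headers must follow the pipe-separated dialect
#' `species_id|accession|gene_symbol`. One record is returned per FASTA
#' entry; sequences must be non-empty, ungapped amino acid strings (the 20
#' standard letters plus the ambiguity letters X, B, Z).
#'
#' @param path Path to a FASTA file of candidate protein records.
#' @param config Optional [species_config()]; when given, each record is
#'   tagged as `foreground-db` or `reference-db` according to the panel, and
#'   records from species outside the panel are retained with source
#'   `unknown` and a warning.
#' @return A data.frame of records with columns `species_id`, `accession`,
#'   `gene_symbol`, `sequence`, `source`.
#' @export
parse_family_fasta <- function(path, config = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L) stop("malformed FASTA in '", path, "': no entries")
  headers <- names(seqs)
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 3L)
  if (length(bad)) {
    stop("parse error in '", path, "', entry ", bad[[1L]], " ('",
         headers[[bad[[1L]]]],
         "'): header must be 'species_id|accession|gene_symbol'")
  }
  empty <- which(Biostrings::width(seqs) == 0L)
  if (length(empty)) {
    stop("parse error in '", path, "', entry ", empty[[1L]], " ('",
         headers[[empty[[1L]]]], "'): empty sequence")
  }
  sequence <- as.character(seqs)
  gapped <- grepl("-", sequence, fixed = TRUE)
  if (any(gapped)) {
    stop("validation error in '", path, "', entry ", which(gapped)[[1L]],
         " ('", headers[[which(gapped)[[1L]]]],
         "'): record sequences must be ungapped")
  }
  rec <- data.frame(
    species_id = trimws(vapply(parts, `[[`, "", 1L)),
    accession = trimws(vapply(parts, `[[`, "", 2L)),
    gene_symbol = trimws(vapply(parts, `[[`, "", 3L)),
    sequence = unname(sequence),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(rec$species_id)))
    stop("parse error in '", path, "': empty species_id field")
  if (any(!nzchar(rec$accession)))
    stop("parse error in '", path, "': empty accession field")
  rec$source <- "reference-db"
  if (!is.null(config)) {
    rec$source <- ifelse(rec$species_id %in% config$foreground, "foreground-db",
                         ifelse(rec$species_id %in% config$outgroup,
                                "reference-db", "unknown"))
    unk <- unique(rec$species_id[rec$source == "unknown"])
    if (length(unk))
      warning("records from species outside the configured panel retained ",
              "with source 'unknown': ", paste(unk, collapse = ", "))
  }
  rec
}

#' Write protein records (or alignment rows) as FASTA
#'
#' Uses the same `species_id|accession|gene_symbol` header dialect that
#' [parse_family_fasta()] and [load_msa()] read.
#'
#' @param records Data.frame with `species_id`, `accession`, `gene_symbol`,
#'   `sequence` columns; sequences may be gapped (alignment rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(records$sequence)
  names(seqs) <- paste(records$species_id, records$accession,
                       records$gene_symbol, sep = "|")
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a gene alias table
#'
#' Tab-separated file with two columns and no header: gene symbol, accepted
#' alias. A gene may span multiple lines, one alias per line.
#'
#' @param path Path to the alias TSV.
#' @return Named list mapping gene symbol to a character vector of aliases.
#' @export
read_alias_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("gene", "alias"),
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  split(trimws(tab$alias), trimws(tab$gene))
}

#' Filter candidate records by accepted gene aliases
#'
#' Keeps records whose gene symbol matches (case-insensitively, after
#' whitespace trimming) any accepted alias of `gene`; the gene symbol itself
#' always counts as accepted. An empty or missing alias set keeps all
#' records and raises a warning, mirroring the absence of curated aliases.
#'
#' @param records Record data.frame from [parse_family_fasta()].
#' @param gene Gene symbol the family is being assembled for.
#' @param aliases Named list from [read_alias_table()], or `NULL`.
#' @return The filtered record data.frame; dropped records are reported via
#'   `message()`.
#' @export
filter_by_alias <- function(records, gene, aliases = NULL) {
  accepted <- unique(c(gene, if (!is.null(aliases)) aliases[[gene]]))
  if (is.null(aliases) || is.null(aliases[[gene]]) ||
      length(aliases[[gene]]) == 0L) {
    warning("no accepted aliases for gene '", gene,
            "'; keeping all records")
    return(records)
  }
  norm <- function(x) tolower(trimws(x))
  keep <- norm(records$gene_symbol) %in% norm(accepted)
  if (any(!keep)) {
    message("alias filter for '", gene, "' dropped ", sum(!keep),
            " record(s): ",
            paste(records$accession[!keep], collapse = ", "))
  }
  records[keep, , drop = FALSE]
}

#' Global percent identity between two protein sequences
#'
#' Identity under a deterministic Needleman-Wunsch global alignment with
#' BLOSUM62 scoring, gap open 11 and gap extend 1: the number of identical
#' aligned residue pairs divided by the alignment length (gapped columns
#' included). The pair is canonically ordered before aligning so the value
#' is exactly symmetric in its arguments.
#'
#' @param a,b Ungapped, non-empty amino acid strings.
#' @param gap_opening,gap_extension Gap penalties (positive costs).
#' @return Identity fraction in \[0, 1\].
#' @export
percent_identity <- function(a, b, gap_opening = 11, gap_extension = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("percent_identity: empty sequence")
  if (grepl("-", paste0(a, b), fixed = TRUE))
    stop("percent_identity: sequences must be ungapped")
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / len
}

#' Resolve one record per species by identity to accepted references
#'
#' Among a species' candidate records, selects the one maximizing the mean
#' (or, optionally, the maximum) [percent_identity()] against the accepted
#' reference sequences. Ties are broken by longer sequence, then
#' lexicographically smallest accession, so the choice depends only on
#' record content, never on input order.
#'
#' @param candidates Data.frame of candidate records for a single species.
#' @param references Character vector of accepted reference sequences (or a
#'   record data.frame with a `sequence` column).
#' @param aggregate `"mean"` (default) or `"max"` identity across references.
#' @return The single selected record (one-row data.frame).
#' @export
resolve_species_records <- function(candidates, references,
                                    aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  if (is.data.frame(references)) references <- references$sequence
  if (NROW(candidates) == 0L)
    stop("resolve_species_records: empty candidate list")
  if (length(references) == 0L)
    stop("resolve_species_records: empty reference list")
  agg <- if (aggregate == "mean") mean else max
  score <- vapply(candidates$sequence, function(s) {
    agg(vapply(references, function(r) percent_identity(s, r), 0))
  }, 0, USE.NAMES = FALSE)
  ord <- order(-score, -nchar(candidates$sequence), candidates$accession)
  candidates[ord[[1L]], , drop = FALSE]
}

#' Assemble an ortholog family: one resolved record per species
#'
#' Applies the alias filter, resolves the accepted sequence for each
#' reference species (longest sequence, then smallest accession, among its
#' candidates), then resolves every species' candidates by identity against
#' those accepted references. Records from species outside the configured
#' panel are dropped with a message.
#'
#' @param records Candidate record data.frame (possibly several per species).
#' @param gene_symbol Family gene symbol; resolved records are relabelled
#'   with it so the family is internally consistent even when candidates
#'   carried alias symbols.
#' @param config [species_config()].
#' @param aliases Optional alias list (see [filter_by_alias()]); `NULL`
#'   skips alias filtering.
#' @param aggregate Identity aggregation across references, see
#'   [resolve_species_records()].
#' @return An `ortholog_family` object: `gene_symbol`, `records` (one row
#'   per species, panel order), `config`.
#' @export
resolve_family <- function(records, gene_symbol, config, aliases = NULL,
                           aggregate = "mean") {
  if (!inherits(config, "species_config")) stop("`config` must be a species_config")
  if (!is.null(aliases))
    records <- filter_by_alias(records, gene_symbol, aliases)
  panel <- c(config$foreground, config$outgroup)
  off_panel <- setdiff(unique(records$species_id), panel)
  if (length(off_panel)) {
    message("dropping records from species outside the panel: ",
            paste(off_panel, collapse = ", "))
    records <- records[records$species_id %in% panel, , drop = FALSE]
  }
  if (NROW(records) == 0L)
    stop("no panel records remain for gene '", gene_symbol, "'")

  accepted <- lapply(intersect(config$reference, records$species_id),
                     function(sp) {
    cand <- records[records$species_id == sp, , drop = FALSE]
    ord <- order(-nchar(cand$sequence), cand$accession)
    cand[ord[[1L]], , drop = FALSE]
  })
  accepted <- do.call(rbind, accepted)
  if (is.null(accepted) || NROW(accepted) == 0L)
    stop("no reference-species records available to anchor resolution for '",
         gene_symbol, "'")

  resolved <- lapply(intersect(panel, unique(records$species_id)),
                     function(sp) {
    cand <- records[records$species_id == sp, , drop = FALSE]
    if (NROW(cand) == 1L) cand
    else resolve_species_records(cand, accepted, aggregate = aggregate)
  })
  resolved <- do.call(rbind, resolved)
  resolved$gene_symbol <- gene_symbol
  rownames(resolved) <- NULL
  structure(
    list(gene_symbol = gene_symbol, records = resolved, config = config),
    class = "ortholog_family"
  )
}

#' Does the family carry a record for every foreground species?
#'
#' Families missing any foreground species are excluded from substitution
#' calling: clade-unique variants are untestable when part of the clade is
#' absent.
#'
#' @param family An `ortholog_family`.
#' @return Logical scalar.
#' @export
has_complete_foreground <- function(family) {
  all(family$config$foreground %in% family$records$species_id)
}

#' @export
print.ortholog_family <- function(x, ...) {
  cat("ortholog_family '", x$gene_symbol, "': ", NROW(x$records),
      " species (", sum(x$records$species_id %in% x$config$foreground),
      " foreground)\n", sep = "")
  invisible(x)
}
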