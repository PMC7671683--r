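REPORT_VERSION <- "cladesubs report v1"

#' @noRd
write_tsv_report <- function(df, path, title) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", REPORT_VERSION, " - ", title), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a report written by [run_pipeline()]
#' @param path Report TSV path.
#' @return Data.frame (the versioned header comment is skipped).
#' @export
read_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' @noRd
fmt_num <- function(x) sprintf("%.6f", x)

#' Modal informative outgroup residue of a call
#' @noRd
outgroup_consensus_residue <- function(outgroup_residues) {
  v <- outgroup_residue_vector(outgroup_residues)
  tab <- sort(table(v), decreasing = TRUE)
  ties <- names(tab)[tab == tab[[1L]]]
  sort(ties)[[1L]]
}

#' Scatter table of the pooled scored substitutions
#'
#' One row per substitution with the two plotting axes (JSD conservation and
#' mean foreground-vs-outgroup BLOSUM62), the top-fraction flag, and a
#' highlight mark for user-designated genes of interest.
#'
#' @param scored Pooled data.frame from [rank_and_flag()].
#' @param genes_of_interest Character vector of gene symbols to highlight.
#' @return Data.frame with `gene_symbol`, `column`, `position`, `jsd`,
#'   `mean_blosum`, `flagged`, `highlight`.
#' @export
export_scatter <- function(scored, genes_of_interest = character()) {
  if (NROW(scored) == 0L) stop("export_scatter: empty scored set")
  data.frame(
    gene_symbol = scored$gene_symbol,
    column = scored$column,
    position = scored$position,
    jsd = scored$jsd,
    mean_blosum = scored$mean_blosum,
    flagged = scored$flagged,
    highlight = scored$gene_symbol %in% genes_of_interest,
    stringsAsFactors = FALSE
  )
}

#' External aligner adapter backed by MAFFT
#'
#' Returns a function satisfying the aligner contract (unaligned FASTA in,
#' aligned FASTA out, same headers) by shelling out to `mafft`. Provided as
#' a convenience for running on pre-alignment inputs; the tested pipeline
#' path takes pre-computed alignments.
#'
#' @param args Extra command-line arguments (default `"--auto"`).
#' @return A `function(in_fasta, out_fasta)`.
#' @export
mafft_aligner <- function(args = "--auto") {
  function(in_fasta, out_fasta) {
    status <- system2("mafft", c(args, shQuote(in_fasta)),
                      stdout = out_fasta, stderr = FALSE)
    if (status != 0L) stop("mafft failed with status ", status)
    invisible(out_fasta)
  }
}

#' Run the full substitution scan over a manifest of gene families
#'
#' For each gene: parse candidate records, filter by alias, resolve one
#' record per species by identity against the accepted references, load (or
#' produce) the alignment, compute Henikoff weights, call clade-unique
#' substitutions and foreground-specific indels, and score each call. The
#' calls from all genes are then pooled, percentile-ranked, and the top
#' fraction flagged. Genes failing validation (including families missing a
#' foreground species) are skipped with a logged reason and counted in the
#' run summary.
#'
#' @param manifest Data.frame with columns `gene_symbol`, `fasta` and
#'   optionally `msa` (path to a pre-computed aligned FASTA; `NA` rows are
#'   aligned with `aligner`).
#' @param species [species_config()].
#' @param scoring [scoring_config()].
#' @param aliases Optional alias list from [read_alias_table()].
#' @param out_dir Output directory; receives `substitution_report.tsv`,
#'   `indel_report.tsv`, `scatter.tsv`, `partial_sites.tsv` and
#'   `run_summary.json`.
#' @param genes_of_interest Gene symbols highlighted in the scatter table.
#' @param min_outgroup Minimum informative outgroup species per callable
#'   column (see [detect_substitutions()]).
#' @param aligner Optional aligner adapter, e.g. [mafft_aligner()].
#' @param verbose Per-gene progress messages to stderr.
#' @return Invisibly, a list with `substitutions`, `indels`, `scatter`,
#'   `partial`, `summary`.
#' @export
run_pipeline <- function(manifest, species, scoring = scoring_config(),
                         aliases = NULL, out_dir,
                         genes_of_interest = character(),
                         min_outgroup = 5L, aligner = NULL, verbose = TRUE) {
  stopifnot(is.data.frame(manifest),
            all(c("gene_symbol", "fasta") %in% names(manifest)),
            inherits(species, "species_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)

  subs <- list(); indels <- list(); partial <- list(); skipped <- list()
  n_candidate_records <- 0L
  for (i in seq_len(NROW(manifest))) {
    gene <- manifest$gene_symbol[[i]]
    step <- function(expr, stage) {
      tryCatch(expr, error = function(e) {
        skipped[[gene]] <<- paste0(stage, ": ", conditionMessage(e))
        say("  [skip] ", gene, " (", stage, "): ", conditionMessage(e))
        NULL
      })
    }
    say("gene ", gene, " (", i, "/", NROW(manifest), ")")
    records <- step(suppressWarnings(
      parse_family_fasta(manifest$fasta[[i]], species)), "parse")
    if (is.null(records)) next
    n_candidate_records <- n_candidate_records + NROW(records)
    family <- step(suppressWarnings(suppressMessages(
      resolve_family(records, gene, species, aliases = aliases))), "resolve")
    if (is.null(family)) next
    if (!has_complete_foreground(family)) {
      missing <- setdiff(species$foreground, family$records$species_id)
      skipped[[gene]] <- paste0("missing foreground species: ",
                                paste(missing, collapse = ", "))
      say("  [skip] ", gene, ": missing foreground species ",
          paste(missing, collapse = ", "))
      next
    }
    m <- if ("msa" %in% names(manifest) && !is.na(manifest$msa[[i]])) {
      step(load_msa(manifest$msa[[i]], family), "load_msa")
    } else {
      if (is.null(aligner)) {
        skipped[[gene]] <- "no msa path and no aligner adapter"
        next
      }
      step({
        tin <- tempfile(fileext = ".fasta")
        tout <- tempfile(fileext = ".fasta")
        write_family_fasta(family$records, tin)
        aligner(tin, tout)
        load_msa(tout, family)
      }, "align")
    }
    if (is.null(m)) next
    res <- step({
      w <- henikoff_weights(m)
      calls <- detect_substitutions(m, family$config, min_outgroup)
      list(scored = score_substitutions(m, calls, w, family$config, scoring),
           ind = detect_indels(m, family$config),
           part = detect_partial_sites(m, family$config, min_outgroup))
    }, "detect/score")
    if (is.null(res)) next
    subs[[gene]] <- res$scored
    indels[[gene]] <- res$ind
    partial[[gene]] <- res$part
  }

  pooled <- if (length(subs))
    do.call(rbind, c(subs, list(make.row.names = FALSE))) else NULL
  if (is.null(pooled) || NROW(pooled) == 0L)
    stop("run_pipeline: empty pooled substitution set (",
         length(skipped), " gene(s) skipped)")
  pooled <- rank_and_flag(pooled, scoring)
  pooled$outgroup_consensus <- vapply(pooled$outgroup_residues,
                                      outgroup_consensus_residue, "",
                                      USE.NAMES = FALSE)
  ind_all <- do.call(rbind, c(indels, list(make.row.names = FALSE)))
  part_all <- do.call(rbind, c(partial, list(make.row.names = FALSE)))
  scatter <- export_scatter(pooled, genes_of_interest)

  rep_sub <- data.frame(
    gene_symbol = pooled$gene_symbol,
    column = pooled$column,
    position = pooled$position,
    foreground_residue = pooled$foreground_residue,
    foreground_positions = pooled$foreground_positions,
    outgroup_consensus = pooled$outgroup_consensus,
    outgroup_residues = pooled$outgroup_residues,
    n_outgroup = pooled$n_outgroup,
    jsd = fmt_num(pooled$jsd),
    mean_blosum = fmt_num(pooled$mean_blosum),
    jsd_percentile = fmt_num(pooled$jsd_percentile),
    blosum_percentile = fmt_num(pooled$blosum_percentile),
    composite = fmt_num(pooled$composite),
    flagged = pooled$flagged,
    stringsAsFactors = FALSE
  )
  scat_out <- scatter
  scat_out$jsd <- fmt_num(scat_out$jsd)
  scat_out$mean_blosum <- fmt_num(scat_out$mean_blosum)

  write_tsv_report(rep_sub, file.path(out_dir, "substitution_report.tsv"),
                   "substitutions")
  write_tsv_report(ind_all, file.path(out_dir, "indel_report.tsv"), "indels")
  write_tsv_report(scat_out, file.path(out_dir, "scatter.tsv"), "scatter")
  write_tsv_report(part_all, file.path(out_dir, "partial_sites.tsv"),
                   "partial foreground sites (diagnostic, never scored)")

  summary <- list(
    report_version = REPORT_VERSION,
    n_genes = NROW(manifest),
    n_genes_scored = length(subs),
    n_genes_skipped = length(skipped),
    skipped = if (length(skipped)) skipped else NULL,
    n_candidate_records = n_candidate_records,
    n_substitutions = NROW(pooled),
    n_indels = NROW(ind_all),
    n_partial_sites = NROW(part_all),
    n_flagged = sum(pooled$flagged)
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(substitutions = pooled, indels = ind_all, scatter = scatter,
                 partial = part_all, summary = summary))
}
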