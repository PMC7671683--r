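#' Configuration for the ortholog-family simulator
#'
#' The simulator generates aligned ortholog families with known ground
#' truth: per-column outgroup conservation levels, foreground-clade-unique
#' substitutions of controlled chemical severity, foreground-specific
#' indels, and the nuisance features real ortholog downloads carry (missing
#' species, decoy isoforms, ambiguous residues).
#'
#' @param n_families Number of families to simulate.
#' @param n_columns Alignment columns per family.
#' @param panel [species_config()]; default the 2-foreground / 9-outgroup
#'   ground-squirrel panel.
#' @param conservation_levels Two-point mix of per-column outgroup
#'   conservation levels: each outgroup sequence carries the column
#'   consensus with probability equal to the level, otherwise a background
#'   draw.
#' @param conserved_fraction Probability a column is at the conserved level.
#' @param n_planted_substitutions Clade-unique substitutions planted per
#'   family.
#' @param severity_range Closed interval of allowed BLOSUM62 scores of the
#'   planted foreground residue against the outgroup consensus.
#' @param planted_conservation Optional conservation level forced at
#'   planted columns (`NULL`: use the column's drawn level).
#' @param n_planted_indels Foreground-specific indel events per family.
#' @param indel_length_range Closed interval of indel lengths in columns.
#' @param p_missing_species Probability each outgroup species is absent
#'   from a family.
#' @param p_extra_isoform Probability a species gets a decoy second record
#'   (its true sequence with 5% of residues mutated).
#' @param p_ambiguous Per-residue probability of replacement by `X`.
#' @param seed Master integer seed; each family uses a substream derived
#'   from `(seed, family_index)` so any family is reproducible in isolation.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_families = 100L,
                       n_columns = 300L,
                       panel = ground_squirrel_panel(),
                       conservation_levels = c(0.95, 0.5),
                       conserved_fraction = 0.7,
                       n_planted_substitutions = 1L,
                       severity_range = c(-4, 2),
                       planted_conservation = NULL,
                       n_planted_indels = 1L,
                       indel_length_range = c(1L, 3L),
                       p_missing_species = 0.1,
                       p_extra_isoform = 0.2,
                       p_ambiguous = 0.001,
                       seed = 42L) {
  stopifnot(n_families >= 1L, n_columns >= 1L,
            inherits(panel, "species_config"),
            length(conservation_levels) == 2L,
            all(conservation_levels >= 0 & conservation_levels <= 1),
            conserved_fraction >= 0, conserved_fraction <= 1,
            n_planted_substitutions >= 0L, n_planted_indels >= 0L,
            length(severity_range) == 2L,
            all(indel_length_range >= 1L),
            p_missing_species >= 0, p_missing_species <= 1,
            p_extra_isoform >= 0, p_extra_isoform <= 1,
            p_ambiguous >= 0, p_ambiguous <= 1)
  structure(
    list(n_families = as.integer(n_families),
         n_columns = as.integer(n_columns), panel = panel,
         conservation_levels = conservation_levels,
         conserved_fraction = conserved_fraction,
         n_planted_substitutions = as.integer(n_planted_substitutions),
         severity_range = severity_range,
         planted_conservation = planted_conservation,
         n_planted_indels = as.integer(n_planted_indels),
         indel_length_range = as.integer(indel_length_range),
         p_missing_species = p_missing_species,
         p_extra_isoform = p_extra_isoform,
         p_ambiguous = p_ambiguous, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @noRd
with_substream <- function(seed, index, expr) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed((seed + 7919L * index) %% 2147483647L)
  force(expr)
}

#' Simulate one ortholog family with planted ground truth
#'
#' Per column an outgroup consensus residue is drawn from the background
#' distribution; each outgroup sequence carries the consensus with
#' probability equal to the column's conservation level, otherwise a fresh
#' background draw. At non-planted columns the consensus is guaranteed to be
#' present in the outgroup (so foreground rows, which copy the consensus,
#' can never produce an accidental clade-unique call). At planted columns
#' the foreground residue is chosen so its BLOSUM62 score against the
#' consensus lies in `severity_range` and the residue appears in no outgroup
#' sequence at that column; the consensus is redrawn (bounded retries) if no
#' such residue exists. Planted indels are maximal foreground- or
#' outgroup-gapped column runs. Generation is a pure function of
#' `(seed, family_index)`.
#'
#' @param config [sim_config()].
#' @param family_index 1-based family index; also determines the gene
#'   symbol `SYNGENE<index>`.
#' @return List with elements `family` (the resolved `ortholog_family`),
#'   `msa`, `truth` (list of `substitutions` and `indels` data.frames), and
#'   `candidates` (record data.frame including any decoy isoforms, as the
#'   ingest stage would see it).
#' @export
simulate_family <- function(config, family_index = 1L) {
  stopifnot(inherits(config, "sim_config"), family_index >= 1L)
  with_substream(config$seed, family_index, {
    gene <- sprintf("SYNGENE%04d", family_index)
    fg <- config$panel$foreground
    og <- config$panel$outgroup
    og <- og[stats::runif(length(og)) >= config$p_missing_species]
    if (length(og) == 0L) og <- config$panel$outgroup[[1L]]
    species <- c(fg, og)
    nsp <- length(species)
    nc <- config$n_columns
    smat <- load_substitution_matrix("BLOSUM62")
    bg <- background_distribution("blosum62")

    # reserve indel ranges first, then planted columns outside them
    indel_len <- if (config$n_planted_indels > 0L)
      sample(seq(config$indel_length_range[[1L]],
                 config$indel_length_range[[2L]]),
             config$n_planted_indels, replace = TRUE) else integer(0)
    need <- config$n_planted_substitutions + sum(indel_len) +
      3L * config$n_planted_indels
    if (need > nc)
      stop("n_columns too small for the requested planted events")
    free <- rep(TRUE, nc)
    indels <- list()
    for (k in seq_along(indel_len)) {
      len <- indel_len[[k]]
      starts <- which(vapply(seq_len(nc - len + 1L), function(s) {
        lo <- max(1L, s - 2L); hi <- min(nc, s + len + 1L)
        all(free[lo:hi])
      }, TRUE))
      if (length(starts) == 0L) stop("no room left to place indel ", k)
      s <- if (length(starts) == 1L) starts else sample(starts, 1L)
      kind <- sample(c("foreground-deletion", "foreground-insertion"), 1L)
      indels[[k]] <- data.frame(gene_symbol = gene, column_start = s,
                                column_end = s + len - 1L, kind = kind,
                                stringsAsFactors = FALSE)
      free[max(1L, s - 2L):min(nc, s + len + 1L)] <- FALSE
    }
    planted_cols <- integer(0)
    if (config$n_planted_substitutions > 0L) {
      avail <- which(free)
      if (length(avail) < config$n_planted_substitutions)
        stop("no room left to place planted substitutions")
      planted_cols <- sort(sample(avail, config$n_planted_substitutions))
    }

    levels <- ifelse(stats::runif(nc) < config$conserved_fraction,
                     config$conservation_levels[[1L]],
                     config$conservation_levels[[2L]])
    if (!is.null(config$planted_conservation))
      levels[planted_cols] <- config$planted_conservation

    draw_outgroup_column <- function(consensus, level) {
      hit <- stats::runif(length(og)) < level
      res <- ifelse(hit, consensus, sample(AA20, length(og),
                                           replace = TRUE, prob = bg))
      res
    }

    mat <- matrix("", nrow = nsp, ncol = nc, dimnames = list(species, NULL))
    consensus <- character(nc)
    truth_sub <- list()
    for (j in seq_len(nc)) {
      cons <- sample(AA20, 1L, prob = bg)
      ogres <- draw_outgroup_column(cons, levels[[j]])
      if (j %in% planted_cols) {
        pick <- NULL
        for (try in seq_len(50L)) {
          cand <- AA20[smat[AA20, cons] >= config$severity_range[[1L]] &
                       smat[AA20, cons] <= config$severity_range[[2L]]]
          cand <- setdiff(cand, c(cons, ogres))
          if (length(cand) > 0L) {
            pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
            break
          }
          cons <- sample(AA20, 1L, prob = bg)
          ogres <- draw_outgroup_column(cons, levels[[j]])
        }
        if (is.null(pick))
          stop("severity_range unsatisfiable at column ", j,
               " after bounded retries")
        if (!cons %in% ogres) ogres[[1L]] <- cons
        mat[fg, j] <- pick
        truth_sub[[length(truth_sub) + 1L]] <- data.frame(
          gene_symbol = gene, column = j, foreground_residue = pick,
          outgroup_consensus = cons, severity = smat[pick, cons],
          conservation_level = levels[[j]], stringsAsFactors = FALSE)
      } else {
        if (!cons %in% ogres) ogres[[1L]] <- cons
        mat[fg, j] <- cons
      }
      mat[og, j] <- ogres
      consensus[[j]] <- cons
    }

    for (ind in indels) {
      cols <- ind$column_start:ind$column_end
      if (ind$kind == "foreground-deletion") mat[fg, cols] <- GAP
      else mat[og, cols] <- GAP
    }

    if (config$p_ambiguous > 0) {
      cells <- which(mat != GAP)
      amb <- cells[stats::runif(length(cells)) < config$p_ambiguous]
      mat[amb] <- "X"
    }

    rows <- apply(mat, 1L, paste, collapse = "")
    m <- msa(rows, gene_symbol = gene)
    true_rec <- data.frame(
      species_id = species,
      accession = sprintf("%s-%s-1", gene, species),
      gene_symbol = gene,
      sequence = gsub(GAP, "", rows, fixed = TRUE),
      source = "synthetic", stringsAsFactors = FALSE
    )
    decoy_sel <- stats::runif(nsp) < config$p_extra_isoform
    decoys <- lapply(which(decoy_sel), function(i) {
      d <- true_rec[i, , drop = FALSE]
      chars <- split_chars(d$sequence)
      nmut <- max(1L, round(0.05 * length(chars)))
      at <- sample(seq_along(chars), nmut)
      chars[at] <- vapply(chars[at], function(a) {
        sample(setdiff(AA20, a), 1L)
      }, "")
      d$sequence <- paste(chars, collapse = "")
      d$accession <- sprintf("%s-%s-2", gene, d$species_id)
      d
    })
    candidates <- rbind(true_rec, do.call(rbind, decoys))
    rownames(candidates) <- NULL

    fam_config <- species_config(
      fg, og, intersect(config$panel$reference, species))
    fam_rec <- true_rec
    rownames(fam_rec) <- NULL
    family <- structure(
      list(gene_symbol = gene, records = fam_rec, config = fam_config),
      class = "ortholog_family")

    truth <- list(
      substitutions = if (length(truth_sub)) do.call(rbind, truth_sub)
        else data.frame(gene_symbol = character(), column = integer(),
                        foreground_residue = character(),
                        outgroup_consensus = character(),
                        severity = numeric(), conservation_level = numeric(),
                        stringsAsFactors = FALSE),
      indels = if (length(indels)) do.call(rbind, indels)
        else data.frame(gene_symbol = character(), column_start = integer(),
                        column_end = integer(), kind = character(),
                        stringsAsFactors = FALSE)
    )
    list(family = family, msa = m, truth = truth, candidates = candidates)
  })
}

#' Simulate a multi-family dataset with combined ground truth
#'
#' @param config [sim_config()].
#' @return List with `families` (list of [simulate_family()] results,
#'   indexed by gene symbol) and `truth` (combined `substitutions` and
#'   `indels` data.frames across families).
#' @export
simulate_dataset <- function(config) {
  fams <- lapply(seq_len(config$n_families),
                 function(i) simulate_family(config, i))
  names(fams) <- vapply(fams, function(f) f$family$gene_symbol, "")
  truth <- list(
    substitutions = do.call(rbind, c(
      lapply(fams, function(f) f$truth$substitutions),
      list(make.row.names = FALSE))),
    indels = do.call(rbind, c(
      lapply(fams, function(f) f$truth$indels),
      list(make.row.names = FALSE)))
  )
  list(families = fams, truth = truth)
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Per family, writes the candidate records (including decoy isoforms) as
#' `<gene>.fasta` and the alignment as `<gene>_msa.fasta`, both in the
#' `species|accession|gene` header dialect; writes the combined truth tables
#' as TSV and a manifest the pipeline can run from.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame (`gene_symbol`, `fasta`, `msa`),
#'   invisibly; files land under `dir`.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- do.call(rbind, lapply(dataset$families, function(f) {
    gene <- f$family$gene_symbol
    fa <- file.path(dir, paste0(gene, ".fasta"))
    ma <- file.path(dir, paste0(gene, "_msa.fasta"))
    write_family_fasta(f$candidates, fa)
    rec <- f$family$records
    rows <- data.frame(species_id = names(f$msa$rows),
                       accession = rec$accession[match(names(f$msa$rows),
                                                       rec$species_id)],
                       gene_symbol = gene, sequence = unname(f$msa$rows),
                       stringsAsFactors = FALSE)
    write_family_fasta(rows, ma)
    data.frame(gene_symbol = gene, fasta = fa, msa = ma,
               stringsAsFactors = FALSE)
  }))
  rownames(manifest) <- NULL
  utils::write.table(dataset$truth$substitutions,
                     file.path(dir, "truth_substitutions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$indels,
                     file.path(dir, "truth_indels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
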