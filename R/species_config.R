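#' Species configuration for a substitution scan
#'
#' Declares which species form the foreground clade whose shared, exclusive
#' residues are sought, which species form the outgroup used for the
#' uniqueness test and the BLOSUM62 divergence average, and which species'
#' accepted sequences anchor ortholog record resolution.
#'
#' @param foreground Character vector (length >= 1) of foreground species
#'   ids, e.g. the two ground squirrels `c("ags", "itr")`.
#' @param outgroup Ordered character vector of outgroup species ids.
#' @param reference Character vector of species whose accepted sequences are
#'   used to resolve multi-record species by percent identity; must be a
#'   subset of `c(foreground, outgroup)`. Defaults to the intersection of
#'   `c("hsa", "mmu", "itr")` with the panel, falling back to the first
#'   outgroup species.
#' @return An object of class `species_config`.
#' @examples
#' species_config(c("ags", "itr"),
#'                c("mmu", "rno", "sar", "pab", "hsa", "eca", "bta", "ocu", "ssc"))
#' @export
species_config <- function(foreground, outgroup,
                           reference = NULL) {
  foreground <- as.character(foreground)
  outgroup <- as.character(outgroup)
  if (length(foreground) < 1L || any(!nzchar(foreground)))
    stop("`foreground` must contain at least one non-empty species id")
  if (anyDuplicated(c(foreground, outgroup)))
    stop("foreground and outgroup species sets must be disjoint and duplicate-free")
  panel <- c(foreground, outgroup)
  if (is.null(reference)) {
    reference <- intersect(c("hsa", "mmu", "itr"), panel)
    if (length(reference) == 0L) reference <- panel[[1L]]
  }
  reference <- as.character(reference)
  if (!all(reference %in% panel))
    stop("`reference` species must be a subset of foreground + outgroup")
  structure(
    list(foreground = foreground, outgroup = outgroup, reference = reference),
    class = "species_config"
  )
}

#' @export
print.species_config <- function(x, ...) {
  cat("species_config\n")
  cat("  foreground:", paste(x$foreground, collapse = ", "), "\n")
  cat("  outgroup:  ", paste(x$outgroup, collapse = ", "), "\n")
  cat("  reference: ", paste(x$reference, collapse = ", "), "\n")
  invisible(x)
}

#' The 11-species ground-squirrel study panel
#'
#' Convenience constructor for the default panel: the two ground squirrels
#' (Arctic ground squirrel `ags`, 13-lined ground squirrel `itr`) as
#' foreground and nine other mammals as outgroup, with human, mouse and the
#' 13-lined ground squirrel anchoring record resolution.
#'
#' @return A [species_config()].
#' @export
ground_squirrel_panel <- function() {
  species_config(
    foreground = c("ags", "itr"),
    outgroup = c("mmu", "rno", "sar", "pab", "hsa", "eca", "bta", "ocu", "ssc"),
    reference = c("hsa", "mmu", "itr")
  )
}
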