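#!/usr/bin/env Rscript
# Regenerates the SYNTHETIC ATP5G1-like exemplar bundled under inst/extdata/.
#
# The family is constructed, not downloaded: it mimics the qualitative
# features reported for the real ATP5G1 ortholog family -- a ground-squirrel
# clade carrying three clade-unique substitutions in the N-terminal region
# (a leucine at precursor position 32 replacing an otherwise conserved
# proline, an N->D site at 34, a T->P site at 39), two small
# foreground-specific indels N-terminal of them, and a largely invariant
# C-terminal segment -- plus the ingest nuisances the pipeline must handle
# (a decoy AGS isoform, an alias-labelled human record, an off-alias decoy).
# Every filename carries "synthetic"; nothing here is a real sequence.

suppressMessages(library(cladesubs))

set.seed(20201014)
panel <- ground_squirrel_panel()
AA <- cladesubs:::AA20
n_col <- 70L

# consensus backbone, then engineered features in alignment coordinates
consensus <- sample(AA, n_col, replace = TRUE,
                    prob = cladesubs::background_distribution("blosum62"))
ins_cols <- 8:9     # foreground-insertion (outgroup gapped)
del_cols <- 15L     # foreground-deletion (foreground gapped)
sub_cols <- c(33L, 35L, 40L)  # -> foreground precursor positions 32, 34, 39
consensus[sub_cols] <- c("P", "N", "T")
fg_res <- c("L", "D", "P")

mat <- matrix(rep(consensus, each = 11L), nrow = 11L,
              dimnames = list(c(panel$foreground, panel$outgroup), NULL))

# moderate outgroup variability away from the engineered sites: a few
# species deviate at designated columns, consensus always retained
variable_cols <- setdiff(sample(seq_len(50L), 12L),
                         c(ins_cols, del_cols, sub_cols))
for (j in variable_cols) {
  who <- sample(panel$outgroup, sample(2:4, 1))
  mat[who, j] <- sample(setdiff(AA, consensus[[j]]), length(who),
                        replace = TRUE)
}

mat[panel$foreground, sub_cols] <- rep(fg_res, each = 2L)
mat[panel$outgroup, ins_cols] <- "-"
mat[panel$foreground, del_cols] <- "-"

rows <- apply(mat, 1L, paste, collapse = "")
stopifnot(all(vapply(panel$foreground, function(s) {
  cumsum(strsplit(rows[[s]], "")[[1]] != "-")[[33]] == 32L
}, TRUE)))

records <- data.frame(
  species_id = rownames(mat),
  accession = sprintf("SYNP%02d", seq_len(11L)),
  gene_symbol = "ATP5G1",
  sequence = gsub("-", "", rows, fixed = TRUE),
  stringsAsFactors = FALSE
)
# human record labelled with an accepted alias (exercises the alias filter)
records$gene_symbol[records$species_id == "hsa"] <- "ATP5MC1"

# decoy AGS isoform: 4 mutations, resolved away by identity to references
decoy <- records[records$species_id == "ags", ]
chars <- strsplit(decoy$sequence, "")[[1]]
at <- sample(seq_along(chars), 4L)
chars[at] <- vapply(chars[at], function(a) sample(setdiff(AA, a), 1L), "")
decoy$sequence <- paste(chars, collapse = "")
decoy$accession <- "SYNP90"
# off-alias paralog-like record, removed by the alias filter
paralog <- records[records$species_id == "mmu", ]
paralog$gene_symbol <- "ATP5G2"
paralog$accession <- "SYNP91"

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_family_fasta(rbind(records, decoy, paralog),
                   "inst/extdata/atp5g1_synthetic.fasta")
msa_rows <- data.frame(species_id = rownames(mat),
                       accession = records$accession,
                       gene_symbol = records$gene_symbol,
                       sequence = unname(rows), stringsAsFactors = FALSE)
write_family_fasta(msa_rows, "inst/extdata/atp5g1_synthetic_msa.fasta")
writeLines(c("ATP5G1\tATP5G1", "ATP5G1\tATP5MC1", "ATP5G1\tSu9"),
           "inst/extdata/atp5g1_synthetic_aliases.tsv")
cat("wrote inst/extdata/atp5g1_synthetic*{fasta,tsv}\n")
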