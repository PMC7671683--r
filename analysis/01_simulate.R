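#!/usr/bin/env Rscript
# Step 1: generate the benchmark dataset of simulated ortholog families.
#
# 100 families x 300 alignment columns over the 11-species panel (2
# ground-squirrel foreground, 9 mammalian outgroup), one planted
# clade-unique substitution and one foreground-specific indel per family,
# with the ingest nuisances the real download pipeline faces (occasional
# missing outgroup species, decoy isoforms, rare ambiguous residues).
# Writes FASTA + aligned FASTA + truth tables + manifest under
# results/simdata/.

suppressMessages(library(cladesubs))

cfg <- sim_config(n_families = 100, n_columns = 300,
                  n_planted_substitutions = 1, n_planted_indels = 1,
                  p_missing_species = 0.1, p_extra_isoform = 0.2,
                  p_ambiguous = 0.001, seed = 42)
dataset <- simulate_dataset(cfg)
manifest <- write_dataset(dataset, "results/simdata")

cat("families written:  ", nrow(manifest), "\n")
cat("planted subs:      ", nrow(dataset$truth$substitutions), "\n")
cat("planted indels:    ", nrow(dataset$truth$indels), "\n")
nsp <- vapply(dataset$families, function(f) length(f$msa$rows), 0L)
cat("species per family:", min(nsp), "-", max(nsp), "\n")
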