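# Small in-code fixtures shared across tests.

# A 2-foreground / 9-outgroup panel with generic species names.
toy_panel <- function() {
  species_config(c("f1", "f2"), paste0("o", 1:9), reference = c("o1", "f2"))
}

# Build an msa from per-species row strings; foreground rows first.
toy_msa <- function(..., gene = "TOY") {
  msa(c(...), gene_symbol = gene)
}

# One-column alignment from a foreground residue pair and an outgroup
# residue vector (length 9 unless given).
one_column_msa <- function(fg, og, gene = "TOY") {
  rows <- c(stats::setNames(fg, c("f1", "f2")),
            stats::setNames(og, paste0("o", seq_along(og))))
  msa(rows, gene_symbol = gene)
}

# Record data.frame row.
rec <- function(species, accession, sequence, gene = "G1",
                source = "synthetic") {
  data.frame(species_id = species, accession = accession, gene_symbol = gene,
             sequence = sequence, source = source, stringsAsFactors = FALSE)
}

write_fasta_text <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
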