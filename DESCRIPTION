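Package: cladesubs
Title: Detection and Conservation Scoring of Clade-Unique Amino Acid
    Substitutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies amino acid substitutions unique to a foreground clade
    (for example the hibernating ground squirrels) from per-gene orthologous
    protein alignments, and prioritizes them by sequence-weighted
    Jensen-Shannon divergence conservation scores and averaged
    foreground-versus-outgroup BLOSUM62 scores. Includes ortholog record
    resolution by percent identity against accepted reference sequences,
    foreground-specific indel detection, top-percentile candidate flagging,
    and a synthetic ortholog-family simulator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
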