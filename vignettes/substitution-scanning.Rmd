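---
title: "Scanning ortholog families for clade-unique substitutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning ortholog families for clade-unique substitutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladesubs)
```

## The question the pipeline answers

Given orthologous protein sequences for a species panel split into a
foreground clade (here, by default, the Arctic and 13-lined ground
squirrels) and a mammalian outgroup, which amino acid sites carry a residue
shared by the entire foreground clade and absent from every outgroup
species — and which of those sites are the most promising candidates for
functional adaptation? A site is promising when two signals coincide: the
outgroup is strongly conserved there (the clade broke a constraint that held
everywhere else), and the replacement is chemically drastic (a strongly
negative BLOSUM62 score). The composite of the two is what flags a
candidate like a leucine replacing a deeply conserved proline in the
mitochondrial-targeting region of an ATP synthase subunit.

## Procedure and assumptions

The pipeline takes orthology as given: each gene arrives as a set of
candidate records per species plus a protein multiple sequence alignment
(or an external-aligner adapter such as `mafft_aligner()`). Its stages are:

1. *Alias filtering.* Records whose gene symbol is not an accepted alias of
   the target gene are dropped. With no alias table, everything is kept and
   a warning raised — silence would hide a missing curation input.
2. *Record resolution.* One record per species is chosen by maximum mean
   global percent identity against the accepted reference sequences
   (human, mouse, 13LGS by default). Percent identity is defined on a
   deterministic Needleman–Wunsch alignment (BLOSUM62, gap open 11 /
   extend 1) as matches divided by alignment length including gapped
   columns; the sequence pair is canonically ordered first so the value is
   exactly symmetric. Ties break by longer sequence, then smallest
   accession — content-based, so resolution never depends on file order.
   Because the accepted reference sequences themselves must come from
   somewhere, reference species with multiple candidates are resolved
   first, by longest sequence then smallest accession; identity to a
   reference is meaningless before a reference exists. The mean across
   references is the default aggregation; `aggregate = "max"` is available
   since either reading of "maximum percent identity against the accepted
   sequences" is defensible.
3. *Substitution calling.* A column is called iff all foreground species
   show the same standard residue, the residue occurs in no informative
   outgroup species, and at least `min_outgroup = 5` of the outgroup
   species are informative there. Ambiguity letters (X, B, Z) block a call
   when they occur in the foreground and are simply uninformative in the
   outgroup: an X is evidence of nothing, so it neither licenses nor
   vetoes a call. The `min_outgroup` guard exists because "absent from the
   outgroup" is weak evidence when most of the outgroup is missing.
   Near-miss sites where only part of the clade carries a unique residue
   go to a separate diagnostic listing (`detect_partial_sites()`) and are
   never scored.
4. *Indel calling.* Maximal runs of columns gapped in all foreground and
   none of the outgroup (foreground-deletion), or the reverse
   (foreground-insertion). Events are reported but not scored: the
   conservation/severity machinery is defined on residues, not gaps.
5. *Scoring and ranking*, described next.

The uniqueness test is evaluated per alignment column. That is the only
definition compatible with reporting per-residue conservation scores, since
both the uniqueness test and the JSD consume the same column.

## The conservation score

For a call at column *c*, the outgroup residues (default; see below) form a
weighted distribution $p$ over the 20 standard amino acids, with weights
from Henikoff position-based weighting of the full alignment, renormalized
over the contributing species, plus a pseudocount of $10^{-7}$ per residue.
The score is the Jensen–Shannon divergence from a background distribution
$q$:

$$\mathrm{JSD}(p, q) = \lambda\,\mathrm{KL}(p \,\|\, r) +
  (1-\lambda)\,\mathrm{KL}(q \,\|\, r), \qquad r = \lambda p + (1-\lambda) q,$$

with $\lambda = 1/2$ and logarithms base 2, so the score lives in $[0, 1]$
bits and $0\log 0 \equiv 0$. The reported score is scaled by
$(1 - \text{gap fraction})$: a column half-composed of gaps can never look
fully conserved. High JSD means the column distribution is sharp *and* far
from background — a conserved, unusual site.

Choices a reader should know about:

- **Outgroup-only columns by default.** The signal of interest is that the
  site is otherwise highly conserved among the species that did *not*
  change it; including the foreground's divergent residue would dilute
  exactly the signal being measured. Set
  `include_foreground_in_conservation = TRUE` to score the full column.
- **Background** defaults to the amino acid frequencies associated with the
  BLOSUM62 matrix; `uniform` and `alignment`-derived backgrounds are
  options. The choice moves absolute values, not the ranking logic.
- **Windowing is off by default** (`window_radius = 0`). A ±3-column,
  half-weight window in the style of conservation scanning is available
  (`window_radius = 3, window_weight = 0.5`), but windowing answers a
  different question (is the *neighborhood* conserved) than prioritizing a
  single substitution site.
- **Henikoff weights** use $\frac{1}{r_c k_{c,a}}$ averaged over columns;
  all-gap columns are skipped and a sequence's gap positions contribute the
  neutral value $1/n$, which keeps weights defined for gappy rows without
  rewarding or punishing the gaps themselves.

Chemical severity is the arithmetic mean of BLOSUM62 scores of the
foreground residue against the informative outgroup residue multiset.
BLOSUM62 rather than a PAM matrix: log-odds of observed substitutions in
conserved blocks penalize chemically dissimilar replacements, which is the
property being screened for.

## Ranking and the "top 1%"

Percentile ranks (fraction of pooled values at or below) of JSD and mean
BLOSUM62 are computed over the pooled, multi-gene substitution set — each
gene is ranked against the remaining dataset, not against itself. Two flag
modes exist because "top 1% of high JSD and low BLOSUM62" admits two
readings:

- `composite-rank` (default): composite
  $= (\text{jsd pct} + (1 - \text{blosum pct}))/2$; exactly
  $\lceil 0.01\,n \rceil$ items are flagged, ties broken by higher JSD,
  then lower BLOSUM62, then gene symbol, then column — a total order, so
  the flagged set is identical across runs and input orders.
- `quadrant`: flag items jointly at/above the 99th JSD percentile and
  at/below the 1st BLOSUM62 percentile (sample quantiles, type 7). This can
  flag fewer or more than 1% of items.

## Coordinates

Alignment columns are 1-based throughout, matching R's indexing and the
1-based convention of every sequence container in the R ecosystem;
substitutions are additionally reported as 1-based positions in each
foreground species' own precursor (unprocessed protein) sequence, which is
the coordinate in which sites like "leucine-32" are named.

## What the simulator emulates — and what it does not

`simulate_family()` generates a column-level model of an ortholog family:
per column, a consensus residue drawn from the background; each outgroup
sequence carries the consensus with probability equal to the column's
conservation level (a two-point conserved/variable mix, 0.95 with
probability 0.7 and 0.5 otherwise, by default), else a fresh background
draw; foreground rows copy the consensus except at planted columns. Planted
substitutions are constructed to be genuinely clade-unique (resampled until
the chosen residue, with BLOSUM62 severity in the requested range, occurs in
no outgroup sequence at that column), and at every non-planted column the
consensus is guaranteed present in the outgroup, so under nuisance-free
settings the simulator excludes homoplasy *by construction* — which is what
makes exact recovery (sensitivity and precision 1.0) a meaningful detector
check rather than a lucky draw. Nuisance features mirror real ingest:
outgroup species dropped with probability 0.1, decoy isoforms (the true
record with 5% of residues mutated) with probability 0.2, ambiguity letters
at rate $10^{-3}$. Generation is a pure function of `(seed, family_index)`,
so any single family is reproducible in isolation and simulation never
disturbs the caller's RNG stream.

The simulator is deliberately *not* a phylogenetic sequence evolver: there
is no tree, no rate matrix, no branch lengths, and columns are independent.
Passing tests on simulated data therefore demonstrates the pipeline's
correctness on families whose columns are exchangeable and whose
clade-unique sites are unambiguous — it does not demonstrate robustness to
alignment error, to convergent substitutions in the outgroup, or to
correlated rate variation along real proteins. Those failure modes enter
real scans through the upstream aligner and the biology, not through the
arithmetic tested here.

## Numerical and degenerate-input conventions

- Pseudocount $10^{-7}$ per residue keeps KL terms finite; at panel sizes
  of ~10 sequences it shifts scores by well under $10^{-5}$ bits.
- Columns whose contributing set is all gaps raise an error at the scoring
  layer; callable columns cannot reach it because the informative-outgroup
  guard rejects them earlier.
- Empty candidate lists, empty sequences, gapped "ungapped" records, ragged
  alignments, and alignment rows that disagree with the resolved records
  are all hard errors naming the offending entry; a gene failing any of
  them is skipped by the pipeline with a logged reason and counted in the
  run summary, never silently absorbed.
- An all-skipped run (empty pooled set) is an error, not an empty report.
- Reports are tab-separated with a versioned comment header; score columns
  are printed at fixed six-decimal precision, which is what makes repeated
  runs byte-identical.

## Problem sizes

The bundled analyses and acceptance checks use 100 simulated families of
300 columns over the 11-species panel (plus two 50-family datasets for the
prioritization contrast), sizes at which the full suite runs in well under
a minute per stage while leaving the detector no room to be accidentally
right: every one of the 100 planted substitutions and 100 planted indels
must be recovered exactly, with zero false calls, for the recovery checks
to pass.

## Known limitations

- Scores are computed per column independently; compensated or epistatic
  substitution pairs are invisible.
- The uniqueness test is qualitative: one convergent outgroup residue
  vetoes a call even at an otherwise perfect site (by design — it mirrors
  the definition of clade-specific — but it makes calls sensitive to
  outgroup sequencing errors).
- Indel events are detected but not prioritized.
- The BLOSUM62 severity average treats the outgroup multiset as
  exchangeable; it is not phylogenetically corrected, so dense clades of
  near-identical outgroup species influence the mean more than their
  independent information warrants. The Henikoff weighting corrects this
  for the JSD but, following the source convention, not for the BLOSUM62
  average.
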