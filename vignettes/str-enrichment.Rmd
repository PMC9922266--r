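---
title: "Repeat-sum enrichment and STR-based gene fingerprinting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat-sum enrichment and STR-based gene fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strenrich)
```

## The model

A short tandem repeat is a run of adjacent copies of a short DNA motif.
`strenrich` works on trinucleotide repeat units (RUs): with a 4-letter
alphabet there are 4³ = 64 of them, a feature space small enough to
enumerate exhaustively yet biologically meaningful (each unit is a codon,
and several — CAG, GAA, CGG — drive known repeat-expansion diseases).
Three quantities describe a gene's repeat content:

* a **tract** is one maximal run of adjacent copies of a unit at a given
  0-based offset, with its **repeat count** (RC) of copies;
* the **repeat sum** RS(u) of a unit is the sum of the RCs over all of
  its tracts in the gene. This is the package's enrichment metric: unlike
  the longest-repeat statistics common in the STR literature, it
  accumulates *every* tract, so a gene with many moderate runs of a unit
  scores as enriched;
* per unit, the **max**, **min** and **most-common** RC (the latter with
  a first-encountered tie rule) summarise the distribution of tract
  sizes and form the three feature rows used for classification.

The pipeline has four stages: scan → normalize → screen → classify. Each
is exposed as ordinary functions plus a thin command-line wrapper.

## Scanner semantics

`scan_tandem_repeats()` makes a single greedy left-to-right pass. At
cursor `i` it counts the maximal adjacent copies `k` of the
`motif_len`-mer starting there; if `k >= min_rc` it emits the tract and
jumps past it, otherwise it advances by a single nucleotide. Two
consequences are deliberate:

* **jump on emit only.** After a sub-threshold run the cursor moves one
  base, never by the run length, so a qualifying run in a shifted frame
  one base downstream is never missed (the demonstration gene's tract at
  offset 34, one base after a spacer, exercises exactly this).
* **rotation suppression.** Inside an emitted CAT tract the rotations
  ATC and TCA also tandem-repeat, but the jump makes the scanner report
  only the leading frame. The demonstration gene therefore reports CAT
  and AAG only.

Homopolymers and period-1/2 runs are reported in trinucleotide frame
(13 A's is one AAA tract of 4 copies with one leftover base): AAA, CCC
and the like are legitimate members of the 64-unit alphabet. `N` never
matches any unit, so tracts cannot span ambiguous bases; this is our
convention — reference-gene handling of ambiguity codes is rarely stated
in the enrichment literature, and refusing to match is the conservative
choice. The scanner is checked for exact equality against an
independently written nested-loop oracle on a thousand random sequences.

`min_rc = 4` follows the usual human minimum (a unit must occur more
than three times); it is a tunable parameter, as is `motif_len`
(di- or hexanucleotide scans are possible, though the 64-unit default is
assumed by the enumeration helpers). The same `min_rc` also defines the
dataset-inclusion rule (`filter_gene_set()`): a gene enters an analysis
only if some unit reaches it.

## Normalizations

Repeat sums are made comparable by three schemes, applied per gene:
`len` divides by gene length in nucleotides (a between-gene factor —
longer genes carry more repeats; values necessarily fall in (0, 1/3]),
`cnt` divides by the gene's summed repeat sums (within-gene composition;
rows sum to 1), and `mm` maps the repeat-sum range onto [0, 1] via
`(x - min)/(max - min)`. The min-max description admits a second reading
(`x/(max - min)`); we adopt the standard bounded form and define the
degenerate zero-range case (single unit, or all units tied) as 0.
Absent units are recorded as `NA` in enrichment tables, distinct from an
explicit zero — whether absence enters the downstream test as a zero is
a separate choice (below).

## The significance screen

For each of the 64 units the two cohorts' per-gene normalized repeat
sums are compared with a two-sided Mann–Whitney U test. By default only
genes carrying the unit contribute (`zero_fill = FALSE`); setting
`zero_fill = TRUE` instead includes non-carriers as zeros, which turns
the test into a mixture of presence and enrichment. Both modes are
exposed because carrier-only testing asks the cleaner question
("*among genes that have the unit*, is it more enriched?") while
zero-filling uses every gene; the default is carrier-only.

P-values are exact when both samples have at most eight observations —
obtained by exhaustive enumeration of the label permutations, with
midranks handling ties — and otherwise come from the normal
approximation with tie and continuity correction (`stats::wilcox.test`).
The crossover point mirrors the behaviour of the standard scientific
Python stack whose defaults most practitioners' numbers reflect, and at
those sample sizes enumeration is both exact and instant.

The 64 raw p-values are corrected with the adaptive two-stage linear
step-up procedure at q = 0.1: stage one runs the step-up test at
q′ = q/(1+q) and uses its rejection count r₁ to estimate the number of
true nulls m₀ = m − r₁; stage two re-tests at q′·m/m₀. Reported
adjusted p-values are the monotone step-up values scaled by
(m₀/m)(1+q) and clipped to [0, 1], so `p_adj <= q` reproduces the
stage-two decision; they are specific to the chosen q, and may be
*smaller* than the raw p. Two consequences are easy to trip over and are
worth stating: a unit can be rejected at FDR 0.1 while its adjusted p
sits above 0.05 (the `tier` column classifies by adjusted p, the
`significant` flag by the procedure); and the adaptive procedure is not
uniformly more powerful than the plain step-up at the same q — when
stage one rejects nothing the procedure stops, even if the plain
step-up at q would have rejected. What *is* guaranteed, and what the
test suite asserts, is that stage two rejects at least whatever stage
one rejects. The implementation is validated against an independent
transcription of the procedure and against reference values on random
p-vectors. The q = 0.1 level is read as the FDR level of the two-stage
method and is configurable.

`rank_rus()` sorts tested units by ascending adjusted p (most
significant first); the least-significant set is the descending-order
prefix after removing any unit already taken, so the two sets never
overlap. Ties break by ascending raw p and then alphabetically, making
rankings reproducible to the byte.

## Feature extraction

`build_features()` emits exactly three rows per gene — max, min and
most-common RC per selected unit — with 0 encoding absence (the natural
"no enrichment" value, and it keeps matrices dense). The `cnt` and `mm`
feature normalizations reuse the gene's *full* repeat-sum profile for
their denominators, not just the selected columns, so a feature value is
interpretable against the gene's whole repeat content; under `mm` a
repeat count below the gene's minimum repeat sum legitimately maps to a
negative value. Z-scoring (`zsc`) uses per-column sample (n−1) standard
deviations fitted over the whole matrix by default, mirroring the common
fit-once protocol; because that leaks across folds, `evaluate_cv()`
offers `leakage_safe = TRUE`, which refits the column statistics on the
training folds only, and `build_features()` accepts stored `fit_stats`
to transform held-out data. Zero-variance columns map to 0.

## Classification harness

Gene names are the class labels; with three rows per gene, stratified
3-fold cross-validation places exactly one variant row of each gene in
each fold (the variant-to-fold assignment is randomized per seed, since
nothing distinguishes the variants a priori). The SVM comes from
libsvm via `e1071` with `scale = FALSE` (normalization is the feature
builder's job). Multiclass decomposition uses libsvm's native
one-vs-one voting — the same decomposition the mainstream Python SVC
performs internally — rather than one-vs-rest; with hundreds of classes
of three samples each, pairwise problems are also far better
conditioned. Grid search (`C` and `gamma` over 0.1/0.5/1/10, linear and
RBF kernels) scores each cell by mean fold accuracy under the same
seeded folds and breaks ties by grid order; `C = 0.1, gamma = 0.1,
linear` is the recorded default single-cell configuration for quick
runs, not an assertion about new data. Reported metrics are accuracy,
macro precision/recall/F1 (macro is appropriate because the design is
balanced by construction) and the multiclass Matthews correlation
coefficient in its covariance form, which reduces to the classical
binary MCC; degenerate confusion matrices return 0 with a warning.
`holdout_split()` (15% default, floor rule, whole genes only) and
`random_run_sample()` (keep a gene when a uniform draw falls below 1/6)
reproduce the standard tuning-holdout and large-cohort subsampling
protocols; `make_test_sets()` builds the nested evaluation sets that
require a gene to carry at least one top-k most-significant *and* one
top-k least-significant unit.

## The synthetic-data generator

`generate_cohorts()` emulates the statistical structure the screen
assumes: per-unit repeat-count distributions that may differ between
cohorts. Under the default `sim_spec()` each of 60 genes per cohort is
600 nt and carries one tract of each of ten planted units with
RC = 4 + Poisson(2); five of the units gain +4 copies in cohort A. The
defaults were chosen once as a realistic moderate design — repeat
counts in the 4–10 range typical of reference-genome trinucleotide
loci, an effect size comparable to a pathogenic expansion step, and
cohort sizes where a rank test has real but not saturated power — and
all tests and examples run against them. Tracts are laid out in random
order with spacers drawn and *verified* by brute-force scan to plant
nothing and extend nothing, and each finished gene is re-scanned so the
emitted truth table agrees exactly with the scanner. What the generator
does **not** emulate: genomic background repeat content (spacers are
repeat-free by construction, real genes are not), interrupted or
imperfect repeats, length variation between genes, correlated units, or
inter-individual repeat-size variability. Passing recovery tests
therefore show that the pipeline finds planted enrichment shifts under
clean conditions; they do not certify power on real genomes.

## Numerical and design choices

* Coordinates are 0-based with half-open tract spans.
* Carrier summaries define `sd = 0` for a single observation (a point
  mass has no spread) while a unit absent everywhere has undefined
  moments (`NA`).
* Exact Mann–Whitney enumeration switches on at ≤ 8 observations per
  sample; with ties the permutation distribution is over midrank U
  values and the two-sided p is `2·min(P≤, P≥)` capped at 1.
* Ranking ties: adjusted p, then raw p, then alphabetical unit.
* Grid-search ties: first cell in declaration order.
* All randomness (splits, folds, sampling, simulation) flows through
  explicit integer seeds via `withr::with_seed`, leaving the caller's
  RNG untouched; identical seeds give byte-identical artifacts.
* Problem sizes in the shipped checks — 60 + 60-gene cohorts for
  recovery at 50 replicates, 10-gene fingerprint sets, ~1000 random
  sequences for the scanner oracle — were chosen as the smallest designs
  at which the respective statistical claims are stable.

## Limitations

The scanner is a naive exact-repeat detector: it does not model
interrupted repeats and its enumeration-friendly design targets
trinucleotides (longer motifs multiply the unit alphabet). Carrier-only
testing conditions on presence, which can bias the screen if presence
itself differs between cohorts — compare with `zero_fill = TRUE` when
that is plausible. Fingerprinting accuracy measures how distinctive
repeat-count patterns are between the genes at hand; because reference
sequences carry fixed repeat lengths, a classifier trained on them
encodes gene fingerprints rather than population biology.
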