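# strenrich

Short tandem repeats (STRs) — runs of adjacently repeated 1–6 nt DNA motifs
— vary between healthy and disease genes, and trinucleotide repeat
expansions in particular are a hallmark of many neurological disorders
(Huntington's disease, several spinocerebellar ataxias, fragile X).
`strenrich` is an R toolkit for asking whether *repeat enrichment
patterns*, rather than single longest repeats, can serve as statistical
and machine-learning features that distinguish gene cohorts and
fingerprint individual genes.

The package is aimed at computational biologists comparing two gene sets
(e.g. a disease gene family versus a genomic background) delivered as
FASTA.

## The method

For a gene sequence and each trinucleotide repeat unit (RU; there are
4³ = 64), a greedy left-to-right scan reports every maximal tandem tract
with repeat count RC ≥ 4 copies. The per-gene enrichment metric is the
**repeat sum**

> RS(u) = Σ over tracts of unit *u* of RC,

i.e. all tracts of a unit contribute, not only the longest one. Repeat
sums are normalized per gene by length (`len`, RS/L), by composition
(`cnt`, RS/ΣRS) or by the min–max range (`mm`). Each of the 64 units is
then screened between the two cohorts with a two-sided Mann–Whitney U
test, and the 64 p-values are corrected with the adaptive two-stage
linear step-up FDR procedure at q = 0.1. Units ranked by ascending
adjusted p are the *most significant* repeat units (MSRU); the tail of
the ranking gives the disjoint *least significant* set (LSRU).

For classification, each gene contributes three feature rows — the
maximum, minimum and most-common (first-encountered mode) RC per selected
unit, 0 where a unit is absent — normalized by `len`, `cnt`, `mm` or
per-column z-scores, and evaluated with a stratified 3-fold
cross-validated SVM (gene names as class labels) reporting accuracy,
macro precision/recall/F1 and the multiclass Matthews correlation
coefficient.

A synthetic-data generator plants tracts with known repeat counts behind
spacers verified free of unintended tandems, so every stage can be tested
against an exact truth table.

## Worked example

The package ships a fully specified 64-nt demonstration gene with three
CAT tracts and one AAG tract:

```r
library(strenrich)
g <- demo_gene()
scan_tandem_repeats(g$sequence)
#>    ru start rc span
#> 1 CAT     0  6   18
#> 2 CAT    21  4   12
#> 3 CAT    34  4   12
#> 4 AAG    46  4   12
build_profile(g)
#> repeat profile for demo_gene ( 64 nt )
#>   CAT: rs = 14, rc = [6, 4, 4]
#>   AAG: rs = 4, rc = [4]
```

CAT has repeat sum 14 (6 + 4 + 4), max RC 6, min RC 4, most-common RC 4,
and its longest tract spans 18 nt. A full two-cohort run on simulated
data (60 + 60 genes, five units with a planted +4-copy shift in cohort
A):

```r
sim <- generate_cohorts(sim_spec(seed = 11))
res <- adjust_two_stage(mwu_per_ru(build_table(sim$cohort_a, "len"),
                                   build_table(sim$cohort_b, "len")))
rk  <- rank_rus(res, 5, 5)
rk$msru
#> [1] "TTA" "AAG" "ATC" "GTC" "CAT"   # exactly the five shifted units
f <- build_features(sim$cohort_a, rk$msru, norm_scheme = "zsc")
evaluate_cv(f, seed = 11)
#> cross-validated SVM (60 classes, 180 rows, 3 folds, C=0.1 gamma=0.1 kernel=linear)
#>   accuracy 0.983 | macro F1 0.978 | precision 0.975 | recall 0.983 | MCC 0.983
```

The recovered MSRU set is exactly the five planted units, and their
repeat-count fingerprints identify individual genes almost perfectly.
A command-line wrapper (`inst/scripts/str-enrich`) exposes the stages as
`scan`, `summarize`, `test`, `select`, `features`, `classify`,
`simulate` and `pipeline` commands; see `?run_command`.

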