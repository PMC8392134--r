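# panelval

Analytical validation of NGS-based germline testing for hereditary
pheochromocytoma/paraganglioma (PPGL) and related endocrine tumor genes,
built around allele-balance quality control of heterozygous calls.

Clinical laboratories validate a targeted panel or exome assay by sequencing
samples with Sanger-established variants and tuning the variant filters
until every known variant is recovered (100% sensitivity) with as few
spurious calls as possible. `panelval` implements that workflow for
laboratory scientists and bioinformaticians:

* **Allele-fraction statistics** — for a heterozygous call with `ref`/`alt`
  read counts, the alt-read fraction `alt/(ref+alt)` (ideal 0.5) and the
  balance ratio `100·min/max` percent (ideal 100%; 15/20 reads → 75%), plus
  the *tightest symmetric window* `[50−d, 50+d]%` with
  `d = max|fraction − 0.5|` over a call set — the narrowest acceptance
  window that keeps sensitivity at 100%.
* **A seven-stage filter cascade** with a per-stage audit trail: panel
  region (± 30 bp intronic padding), consequence (UTR/intronic/synonymous,
  with ±2 bp splice-site rescue), population frequency (> 1% MAF),
  concordant-benign annotation, per-allele depth, a reference-mismatch
  artifact blacklist (the *MEN1* rs2959656 phenomenon), and the
  allele-fraction window.
* **Truth-set concordance** — TP/FP/FN/TN with sensitivity and specificity,
  per-variant or per-position negatives, window × platform sensitivity
  grids, and window optimization.
* **Coverage** — per-gene mean depth over merged CDS intervals
  (`samtools bedcov` semantics, zero-filled) and under-coverage flagging.
* **Read-backed phasing** — cis/trans/ambiguous from a read × variant
  support matrix.
* **Cohort summaries** — diagnostic yield (by clinical class or gene-carrier
  status) and novel-variant tallies.
* **Synthetic data** — a seeded simulator (negative-binomial depth,
  binomial/beta-binomial allele fractions, skewed artifacts, a
  reference-mismatch locus in every sample) and deterministic fixtures
  reconstructing a published validation study's per-variant tables.

## Worked example

Run the full cascade on the packaged panel-validation fixture (15 samples,
155 coding calls) and score it against its truth set:

```r
library(panelval)

fx  <- build_v1_validation_fixture()
res <- run_cascade(fx$calls, panel = fx$panel, profile = fx$profile,
                   config = filter_config(blacklist = fx$blacklist))
res$audit
#>   stage        n_in n_removed n_out
#> 1 region        155         0   155
#> 2 consequence   155         0   155
#> 3 common        155         2   153
#> 4 benign        153         0   153
#> 5 depth         153         0   153
#> 6 blacklist     153        15   138
#> 7 afr           138        98    40
```

The audit shows the cascade at work: 2 common polymorphisms fall to the MAF
stage, the reference-mismatch artifact is removed once per sample (15), and
the 30–70% allele-fraction window eliminates 98 imbalanced artifact calls,
leaving 40 reportable calls. Scoring against the verified pathogenic truth
set and the artifact universe:

```r
compare_to_truth(res$kept, fx$truth[fx$truth$verified_pathogenic, ])
#>   tp fp fn tn sensitivity specificity
#>   12 28  0 NA         100          NA

compare_to_truth(res$kept, fx$truth, universe = fx$calls)
#>   tp fp fn  tn sensitivity specificity
#>   39  1  2 113        95.1        99.1
```

All 12 verified pathogenic variants survive (sensitivity 100%) and 113 of
the 114 artifact calls are eliminated (specificity 99.1%).

Window optimization from printed per-variant read counts:

```r
t1 <- build_table1_fixture()
tightest_symmetric_window(
  t1$calls[t1$calls$platform == "Complete Genomics", ], "integer")
#> <afr_window> [27, 73]% (symmetric)
tightest_symmetric_window(
  t1$calls[t1$calls$platform == "Agilent SureSelect", ], "one_decimal")
#> <afr_window> [44.8, 55.2]% (symmetric)
```

A command-line wrapper is installed at `exec/panelval`
(subcommands `filter`, `validate`, `simulate`, `coverage`, `phase`,
`yield`):

```sh
Rscript "$(Rscript -e 'cat(system.file("exec", "panelval", package = "panelval"))')" \
  filter --calls calls.tsv --panel panel.bed --out run/
```

See `vignettes/panel-validation-methods.Rmd` for the model, the filter
semantics, and every numerical choice.

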