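---
title: "Allele-balance QC and analytical validation of targeted germline panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-balance QC and analytical validation of targeted germline panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelval)
```

## The problem

Hereditary pheochromocytoma/paraganglioma (PPGL) and related endocrine tumor
syndromes are dominated by germline variants in a panel of susceptibility
genes (*SDHB*, *SDHD*, *SDHC*, *VHL*, *RET*, *NF1*, *TMEM127*, *MAX*, *FH*,
and others). Clinical laboratories validate an NGS assay for these genes by
sequencing samples whose variants were previously established by Sanger
sequencing, and then tuning the bioinformatic filters until every known
variant is recovered (100% sensitivity) with as few spurious calls as
possible (specificity).

`panelval` implements that validation workflow end to end: allele-balance
statistics for heterozygote quality control, an auditable variant-filter
cascade, truth-set concordance, per-gene coverage summaries, read-backed
cis/trans phasing, cohort diagnostic-yield summaries, and a synthetic-data
generator plus deterministic fixtures so the whole pipeline is testable at
desk scale without access to patient data.

## The allele-balance model

A germline variant in a dominant tumor gene is heterozygous, so a true call
should draw roughly half of its reads from each allele. Two statistics
quantify the balance of a call with `ref_reads` = $r$ and `alt_reads` = $a$:

* the **alt-read fraction** $f = a/(r+a)$, ideally $0.5$; and
* the **balance ratio** $100\cdot\min(r,a)/\max(r,a)$ percent, ideally 100%
  (for a call with 15 and 20 reads it is 75%).

The two are deterministic functions of each other
($\mathrm{balance} = 100\,\min(f,1-f)/\max(f,1-f)$), and the package tests
that identity on random counts. All window logic operates on the alt-read
fraction, which is the quantity whose per-call values and per-platform
windows are reproducible from published per-variant tables; the balance
ratio is reported alongside because laboratories quote it in worked
examples.

Under a pure binomial model, $a \sim \mathrm{Bin}(d, 0.5)$ at depth $d$.
Real platforms are overdispersed to varying degrees; the simulator uses a
beta-binomial with intra-class correlation $\rho$
($a \sim \mathrm{BetaBin}(d, \alpha=\alpha)$ with
$\alpha = (1-\rho)/(2\rho)$), recovering the binomial at $\rho = 0$.
Platforms with larger $\rho$ spread their heterozygous fractions more widely
and therefore need wider acceptance windows — exactly the pattern seen when
one library preparation requires a 27–73% window while another is served by
roughly 45–55%.

### Acceptance windows

A symmetric allele-fraction window $[50-d, 50+d]$ percent accepts a
heterozygous call when its fraction lies inside, **bounds inclusive**: the
published exclusion rule is "less than 0.3 or higher than 0.7", so a
fraction of exactly 0.30 passes a 30–70% window.

`tightest_symmetric_window()` computes
$d = \max_i |f_i - 0.5|$ over a call set and returns $[50-100d,\,50+100d]$,
the narrowest symmetric window that accepts every call — the window a
laboratory "optimizes" to keep sensitivity at 100%. Bounds are rounded
**outward** (lower bound down, upper bound up) at the reporting precision
(whole percent or one decimal). We chose outward rounding over plain
half-up rounding deliberately: half-up can round a lower bound upward past
the binding call, producing a reported window that excludes a call it was
computed from; outward rounding preserves containment, makes the result
identical to a brute-force narrowest-containing-window scan on the
reporting grid (a property the test suite asserts), and reproduces all
printed bounds that are arithmetically consistent (27–73 at integer
precision, 44.8–55.2 at one decimal). One published bound (45.4–54.6) is
*not* consistent with any containing-window definition — one of the three
printed calls sits at 45.3% — and the package documents the discrepancy in
a test rather than special-casing it.

Ties in the maximum deviation are all reported (attribute `"binding"`, in
input order).

## The filter cascade

`run_cascade()` applies up to seven stages in a fixed order:

| stage | rule | unknown-annotation policy |
|---|---|---|
| region | inside a panel interval ± intronic padding (30 bp default, inclusive) | — |
| consequence | drop UTR / intronic / synonymous | kept + flagged |
| common | drop known MAF strictly > 1% | kept |
| benign | drop ACMG benign ∧ PolyPhen benign ∧ SIFT consistent | kept |
| depth | het: both alleles ≥ minimum; hom: alt only | unknown zygosity tested as hom |
| blacklist | exact-match known artifact loci | — |
| afr | alt fraction inside the window, inclusive | — |

Design choices worth spelling out:

* **Unknown annotations are retained.** A diagnostic pipeline must never
  discard a variant because an annotator failed; every stage that tests an
  annotation declares this policy.
* **Splice-site rescue.** Calls within 2 bp of an exon boundary (HGVS
  offsets ±1/±2, e.g. `c.286+2T>A`) are never removed as intronic, because
  published validation cohorts report such calls as likely pathogenic
  despite an "introns excluded" rule.
* **The benign rule is a strict conjunction** and the SIFT clause defaults
  to "score ≥ 0.05" (i.e. *not* predicted deleterious). Validation
  protocols are sometimes printed with the SIFT inequality in the
  deleterious direction inside a benign rule, which would discard damaging
  variants; the direction is therefore a configuration switch
  (`sift_deleterious_is_benign`), defaulting to the safe reading.
* **The blacklist models reference-mismatch artifacts**: positions where
  the reference genome carries a minor allele, so nearly every sample
  yields a spurious heterozygous "variant" (the *MEN1* rs2959656
  phenomenon). Exact allele matching; removals carry the entry's note.
* **Stage order is fixed only for auditability.** Every stage is a pure
  set predicate, so the final surviving set is invariant under stage
  permutation; the suite asserts this on the packaged fixture. The audit
  telescopes (each stage's survivors are the next stage's input) and every
  input call lands exactly once in the survivors or one stage's removals.

## Truth-set concordance

Calls match truth records by (sample, chrom, pos, ref, alt) after allele
normalization (shared suffix then shared prefix trimmed, position shifted),
which canonicalizes padded indel and delins spellings. Full left-alignment
against a reference sequence is out of scope — the package consumes calls,
not a genome — and the vignette notes this as the known limit of the
normalizer.

In per-variant mode, sensitivity is $100\cdot TP/(TP+FN)$ over truth
variants. Specificity needs a negative universe, which published validation
studies rarely define precisely; the package supports two readings:

* **per-variant** (default): negatives are the artifact calls of the
  pre-filter universe, and $TN$ counts those eliminated by the cascade.
  This is the reading that reproduces a specificity of 113/114 = 99.1% on
  the packaged validation fixture.
* **per-position**: negatives are the Sanger-confirmed wild-type bases of
  the truth spans (the 3569-nucleotide style of denominator), with false
  positives inside the spans subtracted.

`window_grid()` evaluates platforms × windows with only the
allele-fraction filter applied — the table a laboratory prints when
choosing a window — and `optimize_window()` returns the tightest symmetric
window over the truth-matched calls, which by construction restores 100%
sensitivity (and one rounding step narrower fails; asserted in the suite).

## Coverage

`gene_mean_depth()` follows `samtools bedcov` semantics: sum of per-base
depth over the gene's CDS intervals divided by total length, with absent
positions counted as zero and overlapping intervals merged first so a base
contributes once. The standard deviation is the per-base population SD
within a platform; an across-samples SD is the plausible alternative
reading of published mean ± SD coverage figures, and is not computed here.
Since published per-gene depth values are figure-only, the module's
verification is property-based (split invariance, length-weighted means,
simulator recovery within 3 SE) plus the qualitative check that a
capture-depressed profile ranks *SDHA*/*SDHC*/*SDHD* lowest, mirroring the
known weakness of one exome capture design.

## Phasing

`phase()` decides cis/trans/ambiguous from a read × variant support matrix.
Informative reads cover ≥ 2 sites; a read is concordant when it is all-alt
or all-ref at its covered sites. Cis requires concordance ≥ 0.9 with ≥ 5
reads in both the all-alt and all-ref classes (the half-mutant/half-normal
haplotype picture); trans requires near-disjoint alt support with the same
threshold and per-variant minimum; everything else — including zero
informative reads — is ambiguous, not an error. The thresholds are this
package's defaults (tolerant of sequencing error while requiring real
evidence on both haplotype classes); published phasing evidence of this
kind is presented visually, with no printed thresholds to adopt. The
statistic depends only on co-segregation, so read/variant permutation and a
global alt↔ref relabel cannot change a cis verdict (asserted as
properties).

## Synthetic data and the packaged fixtures

The simulator (`simulate_calls()`) draws, per sample: true heterozygous
calls (negative-binomial depth around the platform mean — dispersion `Inf`
pins depth at the mean —, binomial or beta-binomial alt reads), Poisson
artifact calls whose fractions are drawn 85% outside [0.3, 0.7] and 15%
inside, and one reference-mismatch call per sample. Truth records are
consistent with the generated calls by construction, and a fixed seed gives
byte-identical output files. A `clean` switch emits true calls perfectly
balanced and adequately covered, used to assert that no filter can remove a
truth variant under ideal conditions. The default panel is a synthetic
15-gene design with 1 kb of CDS per gene — large enough for thousands of
distinct loci and fast per-base depth tables at test scale; the simulator
does not model read-level artifacts, mapping ambiguity, GC bias within
genes, or CNVs, so passing tests say nothing about those failure modes in
real data.

Three deterministic fixtures reconstruct published per-variant data:

* `build_table1_fixture()` — 20 WES samples, 13 mutation carriers with the
  exact printed read-count pairs across three library preparations (the
  inputs from which the 27–73% and 44.8–55.2% windows are recomputed).
* `build_v1_validation_fixture()` — 15 panel samples, 155 coding calls:
  41 true (12 pathogenic, 2 VUS, 25 benign-classified polymorphisms, 2
  common polymorphisms removed by the MAF stage), 114 artifacts (15
  reference-mismatch, 98 out-of-window, exactly 1 in-window). The published
  aggregate counts do not close exactly (41 true calls versus 12 + 2 + 25
  retained); this builder encodes the one reading that reproduces both the
  100% sensitivity over the verified pathogenic set and the 113/114
  specificity, and every such constant is explicit in its body. Genomic
  coordinates in both fixtures are synthetic placeholders.
* `build_cohort_fixtures()` — the cohort tables as packaged TSVs: 76
  panel-tested patients with per-variant clinical classifications, and the
  novel-variant table (6 patients, 8 variants). Diagnostic yield supports
  two counting modes because the published per-cohort counts mix them: by
  clinical classification (10/37 = 27%) and by gene-carrier status
  (9/24 = 37.5% for *SDHB*/*NF1*, which counts one carrier whose variant is
  classified VUS).

## Worked example

```{r example}
fx <- build_v1_validation_fixture()
res <- run_cascade(fx$calls, panel = fx$panel, profile = fx$profile,
                   config = filter_config(blacklist = fx$blacklist))
res$audit

compare_to_truth(res$kept, fx$truth[fx$truth$verified_pathogenic, ])
compare_to_truth(res$kept, fx$truth, universe = fx$calls)
```

## Numerical choices and degenerate inputs

* Zero total reads is an explicit "no coverage" error, never 0/0.
* Report floats are fixed-precision (percentages 1 dp, fractions 2 dp) with
  half-away-from-zero rounding, so identical results are byte-identical on
  disk.
* Window bounds carry a `1e-9` float-noise guard so exact-grid bounds are
  not pushed one step outward by representation error.
* Empty inputs: an empty call set is valid almost everywhere (filters,
  reports); the tightest window and diagnostic yield of an empty set are
  errors (undefined quantities); phasing with no informative reads is
  `ambiguous` with zero evidence.
* Test problem sizes are deliberate desk-scale choices: the binomial
  false-negative check uses 10,000 simulated heterozygotes at depth 40
  (closed-form tail mass as the oracle, 3-SE agreement), Monte-Carlo
  phasing uses 40 replicates of 80 reads, and brute-force confusion oracles
  run on ≤ 50-call instances.
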