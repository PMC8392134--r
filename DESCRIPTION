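Package: panelval
Title: Analytical Validation of Targeted NGS Panels for Hereditary Tumor Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analytical validation of germline variant calling on
    targeted gene panels and exomes, built around allele-balance quality control
    of heterozygous calls. Provides allele-fraction statistics and
    tightest-symmetric-window optimization, an auditable multi-stage variant
    filter cascade (region, consequence, population frequency, benign
    annotation, depth, reference-mismatch blacklist, allele-fraction window),
    truth-set concordance with sensitivity and specificity, per-gene coverage
    summaries over CDS intervals, read-backed cis/trans phasing of co-occurring
    variants, cohort diagnostic-yield summaries, and a synthetic-data generator
    with deterministic validation fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    readr,
    rlang,
    vcfR,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
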