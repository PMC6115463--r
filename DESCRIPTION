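Package: phosksea
Title: Kinase-Set Enrichment and Prognostic Stratification for Phosphoproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for phosphoproteomics-driven analysis of
    triple-negative breast cancer cohorts: empirical-Bayes differential
    phosphosite selection, linear-motif mapping of phosphosite flanking windows,
    GSEA-style kinase-set enrichment (KSEA) with permutation-based normalized
    enrichment scores and FDR, immunohistochemistry H-score computation with
    75th-percentile K-high prognostic classification and kinase activation
    pattern taxonomy, Kaplan-Meier/Cox survival assessment, and preclinical
    tumor-growth-inhibition scoring. Ships a synthetic-data module that
    generates every input with planted ground truth so each stage has a
    recoverable answer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    survival,
    limma,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    broom,
    withr,
    knitr
Config/testthat/edition: 3
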