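Package: pgsrisk
Title: Polygenic Scores Added to Clinical Models for Predicting Disease Incidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating what a polygenic score (PS) adds to
    clinical variables when predicting incident disease in longitudinal
    cohorts. Builds weighted-allele-sum scores from GWAS summary
    statistics (allele harmonisation, quality-control filters,
    pruning-and-thresholding variant selection, cross-validated
    population-specific weights and variants, principal-component
    residualisation), fits Cox proportional-hazards models with a
    Breslow baseline cumulative hazard to obtain predicted cumulative
    incidence at fixed horizons, and quantifies the increment from the
    score via Harrell's C / AUC differences, continuous net
    reclassification improvement with bootstrap confidence intervals,
    and decision-curve net benefit for censored outcomes. Includes a
    synthetic-cohort generator with overlapping birth, youth and adult
    cohorts and a person-level bootstrap test for differences in PS
    hazard ratios between overlapping cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
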