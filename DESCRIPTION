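Package: haisac
Title: Scoring and Psychometric Validation of the HAI-SAC Cognitive Screen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the scoring rules of the HAI-SAC cognitive screening
    instrument (three objective memory subtests plus two informant-based
    questions) together with the psychometric validation pipeline used to
    evaluate screening tests for Alzheimer's disease staging: Cronbach's
    alpha, Kaiser-Meyer-Olkin sampling adequacy, Bartlett's sphericity test,
    exploratory factor analysis by iterated principal-axis extraction with
    varimax-then-promax rotation, one-way ANOVA (from raw data or printed
    summary statistics) with Bonferroni-corrected contrasts, chi-square
    independence tests, Pearson correlations with strength bands, Steiger's
    test for dependent correlations, empirical ROC curves with Youden-index
    cutoffs, binormal analytic AUC, and DeLong's test for paired AUC
    comparison. A seeded synthetic-cohort generator, calibrated from
    published per-group summary statistics of a three-group memory-clinic
    sample (cognitively unimpaired, mild cognitive impairment, dementia of
    the Alzheimer's type), makes every stage of the pipeline testable
    without patient data.
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
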