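Package: pvror
Title: Pharmacovigilance Signal Screening with Reporting Odds Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for disproportionality analysis of spontaneous
    adverse-event reports in the style of FDA Adverse Event Reporting System
    (FAERS) dashboard exports. Provides case-report ingestion and validation,
    rule-based deduplication, ATC-prefix exclusion filtering, exposure
    classification, reporting odds ratio (ROR) screening with Wald confidence
    intervals at Preferred Term, High-Level Group Term and System Organ Class
    levels, time-to-onset analysis, k-nearest-neighbour imputation with
    univariate logistic-regression risk factors, fatal-case characterisation,
    and a synthetic spontaneous-report generator with planted reporting odds
    ratios for end-to-end validation.
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
    tibble,
    tidyr,
    tools,
    utils,
    vctrs,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
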