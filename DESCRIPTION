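Package: arindex
Title: Adiponectin-Resistin and IR_AR Composite Indexes for Insulin Resistance Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the adiponectin-resistin (AR) composite adipokine index
    and the derived IR_AR insulin-resistance index together with the classical
    surrogate insulin-sensitivity indexes (QUICKI, HOMA-IR, Bennett, McAuley),
    classifies subjects into published risk bands, and provides the full
    case-control evaluation harness: ANCOVA and MANCOVA general linear models
    with an age covariate and Type III sums of squares, pairwise group
    contrasts with stratified bias-corrected and accelerated (BCa) bootstrap
    intervals, and Spearman rank correlation matrices. A calibrated synthetic
    cohort generator emulates the four-group case-control design
    (controls, metabolic syndrome, type 2 diabetes, and both) across three
    ethnic strata so the whole pipeline is testable without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
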