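Package: metsdx
Title: Adiposity and Lipid Indexes as Screening Tools for Metabolic Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes anthropometric and lipid-based adiposity indexes (BMI,
    body adiposity index, lipid accumulation product, cardiometabolic index),
    classifies metabolic syndrome from the International Diabetes Federation
    component thresholds with treatment overrides, and evaluates each index as
    a screening test by receiver operating characteristic analysis with
    Youden-index cutoff selection, DeLong confidence intervals, and likelihood
    ratios, stratified by sex and age.  Includes a Gaussian-copula synthetic
    cohort generator calibrated to published per-sex summary statistics of a
    severely obese adult population, so the full pipeline is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
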