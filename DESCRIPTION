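Package: cecmr
Title: Two-Sample Mendelian Randomization of Cholesterol Efflux Capacity
    on Coronary Artery Disease and Ischemic Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators and diagnostics for two-sample Mendelian
    randomization (MR) with GWAS summary statistics, built around the
    causal analysis of HDL cholesterol efflux capacity (CEC) on coronary
    artery disease, myocardial infarction, ischemic stroke and its
    subtypes. Provides Wald-ratio, inverse-variance weighted (IVW),
    MR-Egger, simple- and weighted-median and multivariable IVW
    estimators; Cochran Q and I-squared heterogeneity within an
    instrument set and between outcome-specific causal estimates;
    instrument-strength summaries (variance explained, F statistic) and
    a binary-outcome power approximation; harmonization of exposure and
    outcome summary rows to a common effect allele; a synthetic
    two-sample summary-statistic generator for estimator validation; and
    the published CEC, coronary and stroke association tables as
    plain-text fixtures.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
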