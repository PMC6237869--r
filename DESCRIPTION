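Package: bittermr
Title: Two-Sample Mendelian Randomization of Bitter Taste Perception and
    Bitter Beverage Consumption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate the causal effect of bitter taste perception
    (propylthiouracil, quinine and caffeine intensity ratings) on coffee,
    tea and alcohol consumption with single-instrument two-sample Mendelian
    randomization. Implements the Wald ratio estimator with delta-method
    standard errors, causal odds ratios for drinker-status contrasts,
    instrument-strength F statistics, power calculations and
    subgroup-difference tests, together with per-allele SNP-phenotype
    association fitting (linear and logistic, covariate adjusted), beverage
    phenotype harmonization (alcohol frequency recoding, repeat-assessment
    averaging, percentile and fixed drinker-status dichotomization), and a
    calibrated synthetic two-cohort generator standing in for the taste
    GWAS discovery sample and a UK-Biobank-like consumption cohort so that
    the full pipeline is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
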