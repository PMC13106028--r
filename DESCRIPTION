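Package: copdwl
Title: Weight-Loss Phenotyping and Genetic Association in COPD Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end toolkit for studying weight loss (the major
    criterion for cachexia) in chronic obstructive pulmonary disease
    cohorts. Implements two longitudinal weight-loss classifiers (a
    visit-based definition for study-visit cohorts and a cleaning plus
    12-month sliding-window regression algorithm for irregular electronic
    health record data), covariate-adjusted single-variant logistic
    association with minor-allele-count filtering and genomic-inflation
    diagnostics, fixed-effects inverse-variance meta-analysis with
    Cochran's Q and I-squared heterogeneity statistics and per-study
    direction strings, rare-variant gene-level burden testing within
    annotation masks with Fisher's-method cross-study p-value combination,
    and a multi-cohort synthetic data generator that emulates the
    longitudinal and genetic structure these stages assume so the whole
    pipeline is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
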