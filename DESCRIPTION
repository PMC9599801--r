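Package: eegpli
Title: Phase Lag Index Connectivity Analysis for Resting-State EEG Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for phase lag index (PLI) functional-connectivity analysis
    of resting-state EEG in two-group clinical cohorts. Provides a synthetic
    cohort generator with known phase-coupling ground truth, a zero-phase
    preprocessing chain (linked-mastoid re-referencing, band-pass and notch
    filtering, downsampling, epoching, amplitude-based epoch rejection),
    band-specific PLI connectivity matrices via the analytic-signal phase,
    between-group statistics, cross-validated logistic-regression
    discrimination with a permutation-based empirical chance level, and an
    end-to-end study pipeline with tidy outputs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
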