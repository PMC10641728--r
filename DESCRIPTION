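Package: qeegicu
Title: Quantitative EEG Biomarkers for Postoperative Delirium Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative EEG (qEEG) biomarker studies of
    sedated intensive-care patients, built around the feature set used to
    discriminate postoperative delirium after cardiac surgery: spectral
    entropy, amplitude-integrated EEG (aEEG) limits, relative alpha
    variability, relative band powers and the 95% spectral edge frequency.
    Includes a calibrated synthetic multichannel EEG generator whose
    theoretical spectral features can be set to published group profiles,
    a preprocessing and feature-extraction chain, the two-group
    statistical layer (Welch tests, one-way ANOVA, exact and chi-square
    proportion comparisons, two-proportion sample sizes), EDF input and
    output, and an end-to-end simulate/extract/compare pipeline. All
    user-facing results are tidy tibbles with ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
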