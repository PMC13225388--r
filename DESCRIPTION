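Package: radextra
Title: Real-Time Detection and Quantification of Radiopharmaceutical
    Extravasation from Dose-Rate Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of ambient dose-equivalent-rate time series recorded by
    wearable gamma detectors on a patient's arms during radiopharmaceutical
    administration. Pairs injection-arm and contralateral-arm curves into
    sessions, anchors and windows them around the bolus peak, applies
    selective Gaussian smoothing, detects the post-injection plateau with a
    successive-difference stability rule, and extracts the curve metrics used
    to classify an administration as normal or extravasated. Downstream
    quantification converts PET volume-of-interest statistics or SPECT counts
    into decay-corrected residual activity at the injection site, estimates
    the local self-absorbed dose through sphere-model dose factors, and
    derives the multiplicative SUV correction coefficient together with its
    linear calibration against curve metrics. Includes a two-arm curve
    simulator with known ground truth, cohort-level statistics (rank tests,
    covariate screening with Holm adjustment, logistic threshold refitting),
    and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
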