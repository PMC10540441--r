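Package: semiogram
Title: Multidimensional Gait Quantification from Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns a 10-m out-and-back walking trial recorded with three
    inertial measurement units (both feet and the lower back) into 17 gait
    parameters, seven z-scored semiological criterion scores and a radar-chart
    visualization (the "semiogram"). Includes per-foot gait-event detection
    from foot angular velocity, U-turn segmentation by integration of the
    trunk craniocaudal angular velocity with linear drift correction,
    smoothness indices (spectral arc length, log dimensionless jerk), trunk
    harmonic ratios and autocorrelation regularity measures, z-score
    normalization against a packaged normative reference, test-retest
    reliability statistics (ICC(1,1), ICC(3,1), SEM, heteroskedasticity
    screening), group comparison and clinical-scale correlation helpers, and
    a deterministic synthetic-gait generator with ground truth for end-to-end
    validation.
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
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
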