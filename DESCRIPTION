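Package: lamewatch
Title: Lameness Detection in Dairy Cows from Accelerometer and Noseband
    Sensor Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting lameness in dairy cows from leg-mounted
    accelerometer and halter noseband sensor data.  Provides a seeded
    synthetic cohort and behavioral event-stream simulator, bout
    segmentation of posture and stride streams (lying, standing and
    walking bouts with minimum-duration and minimum-stride rules),
    hourly and daily aggregation with weighted means and derived
    locomotion variables (calculated walking speed, lying bout
    duration), two- and four-group comparison statistics with
    normality-based test routing and Dunn's post-hoc test, and
    univariable and multivariable logistic lameness classifiers with
    ROC analysis, correlation-filtered backward selection, and frozen
    published model equations for direct scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
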