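Package: caldera
Title: Evolved Time-Domain Classifiers for Dyskinesia Monitoring from Wearable Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains and applies symbolic classifiers of levodopa-induced
    dyskinesia from raw tri-axial accelerometry recorded by body-worn sensors.
    Cartesian genetic programming evolves mathematical expressions over a
    32-sample sliding window of the acceleration magnitude series; per-segment
    scores are the mean expression output over all overlapping windows and are
    thresholded into clinical severity grades. Includes long- and short-term
    spectral baselines, ROC/AUC model selection with bootstrap confidence
    bands, per-grade threshold calibration, activity-stratified evaluation,
    top-window pattern visualisation, 24-hour episode summaries, and a seeded
    synthetic accelerometry generator with planted graded dyskinesia and
    walking confounders for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
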