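Package: fatiguetrend
Title: Physical Fatigue Trend Estimation from Wearable IMU Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An analysis pipeline for estimating physical-fatigue trends of
    workers from body-worn accelerometer recordings. Raw multi-sensor sessions
    are reduced to total-acceleration series, low-pass filtered, cut into long
    overlapping windows, and summarised by power-spectral-density peak features
    (Welch's method), jerk statistics and standard descriptive statistics,
    normalised against each session's starting baseline. Perceived-effort
    self-reports on a 1-5 scale are linearly interpolated to per-window
    targets and predicted with a random-forest regressor under
    leave-one-session-out cross-validation, with univariate F-value feature
    selection per fold, aggregated Gini importances, sensor and feature-family
    ablations, and a multi-model comparison harness. Includes a seeded
    synthetic hauling-session generator so the full pipeline is testable
    without access to the original field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    randomForest,
    rpart,
    glmnet,
    e1071,
    xgboost,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
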