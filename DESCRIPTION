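Package: gaitcast
Title: Predicting Gait-Quality Progression from Kinematic Gait Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying and forecasting gait quality from
    time-normalized kinematic gait cycles. Computes Gait Variable Scores
    (GVS), the Gait Profile Score (GPS) and the Movement Analysis Profile
    against a normative reference, builds supervised datasets of
    improvement/worsening labels from consecutive gait-session pairs
    (signed GPS change), and trains signal-based (1D) and image-based
    (centralized 2D-FFT spectrum) neural classifiers with time-series data
    augmentation (jittering, scaling, window warping, permutation, window
    slicing). Includes a self-contained neural-network engine (dense,
    convolutional, recurrent and attention layers with Adam optimization),
    Mann-Whitney AUC / ROC utilities, DeLong's test for correlated ROC
    curves, and a synthetic gait-cohort generator with planted
    ground-truth progression for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
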