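Package: wristhar
Title: Real-World Human Activity Recognition from Wrist Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, tidyverse-native pipeline for human activity
    recognition (HAR) from a single wrist-worn triaxial accelerometer in
    real-world (in-the-wild) conditions. Provides self-report label-overlap
    correction, signal rescaling and mean-bin downsampling, 12-second
    windowing at 32 Hz, per-participant personalization/hold-out splits with
    leakage gaps, absolute-time chunking into cumulative datasets,
    leave-one-participant-out general models, a compact 1D convolutional
    network with rotational data augmentation and noise regularization,
    transfer-learning personalization with layer freezing, a feature +
    gradient-boosted-trees baseline, the standard evaluation metrics
    (balanced accuracy, F1 variants, logloss), and a synthetic multi-subject
    cohort generator for controlled and real-world regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    signal,
    e1071,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    caret,
    withr
Config/testthat/edition: 3
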