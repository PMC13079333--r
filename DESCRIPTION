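Package: stsynergy
Title: Muscle Synergy Extraction and Anticipatory Sit-to-Stand Motion Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sit-to-stand (SiTSt) and stand-to-sit (StTSi)
    transitions from multi-channel surface electromyography (EMG). Implements
    the full chain from raw EMG to anticipatory motion-state forecasting:
    zero-phase envelope extraction and a causal Kalman alternative for
    real-time use, hip-marker based motion-state segmentation, muscle-synergy
    extraction by (concatenated) non-negative matrix factorization with a
    combined variance-accounted-for / mean-squared-error model-order criterion,
    per-frame non-negative least-squares estimation of temporal synergy
    activations under fixed spatial patterns, a multi-resolution recurrent
    (LSTM) classifier that forecasts the motion state a configurable horizon
    ahead with a learned transition-plausibility stage, and frame-wise
    evaluation (accuracy, class metrics, transition timing error, false
    detection rate, confusion matrices). A synthetic EMG/kinematics generator
    with known latent synergy structure makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
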