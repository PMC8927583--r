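Package: cogload
Title: Cognitive Workload Assessment from EEG and Eye-Tracking Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating operator mental workload
    from synchronized multichannel EEG and eye-tracking recordings. Continuous
    EEG is segmented into 5-second epochs and reduced to normalized spectral
    band-power features (delta, theta, alpha, beta) via Welch periodograms;
    gaze streams are reduced to per-epoch pupillometry and fixation statistics
    (fixation count and duration, scan-path length, nearest-neighbour index).
    Binary low/high workload classifiers -- a stacked bidirectional LSTM over
    band-power sequences and a feed-forward network over fused EEG + eye
    features, with KNN, random-forest and SVM baselines -- are trained with
    Adam on binary cross-entropy and evaluated against input sequence length
    under chronological and session-to-session splits. Scalp topographic maps
    of decibel band-power differences between workload conditions are rendered
    with azimuthal electrode projection and thin-plate interpolation. A
    seeded synthetic physiological-signal generator emulates the two
    acquisition protocols so the whole pipeline runs without recorded
    human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
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
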