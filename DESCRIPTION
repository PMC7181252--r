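Package: fogkit
Title: Freezing-of-Gait Detection from Waist-Worn Triaxial Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete pipeline for detecting freezing-of-gait (FOG) episodes
    in Parkinson's disease from a single waist-worn triaxial accelerometer.
    Provides causal signal preprocessing (polyphase resampling to 40 Hz,
    Butterworth band limiting, sliding-window segmentation with majority
    labeling), three feature representations (hand-crafted freeze-index
    features, inertial mel-frequency cepstral coefficients, and 64-bin FFT
    spectra with contextual stacking of up to three previous windows), novelty
    detectors (one-class SVM, denoising autoencoder) and supervised
    classifiers (SVM, AdaBoost, random forest, 1-D CNN, and a time-distributed
    CNN-LSTM) built on a small self-contained neural-network engine, plus
    leave-one-subject-out and within-subject 10-fold evaluation with
    equal-error-rate metrics. A calibrated synthetic cohort simulator
    generates labeled gait/FOG recordings so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    e1071,
    randomForest,
    rpart,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
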