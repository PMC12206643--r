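Package: eegfusion
Title: Dual-Stream CNN-BiLSTM and Convolutional VAE Modelling of EEG
    Differential-Entropy Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Emotion-state decoding from multi-channel EEG via 4D
    differential-entropy feature organisation (band-pass filtering,
    windowed Gaussian differential entropy, electrode-to-grid topographic
    mapping, six-step temporal stacking) and a dual-stream classifier
    that fuses a CNN-BiLSTM temporal encoder with a deep convolutional
    variational autoencoder, trained under configurable learning-rate
    decay schedules (constant, piecewise exponential, cosine annealing,
    stepped, linear). Includes a class-conditioned synthetic EEG
    generator with per-subject gain and baseline variability so the full
    pipeline is testable without access-controlled recordings, plus
    subject-dependent k-fold and leave-one-subject-out evaluation with
    accuracy and fold standard-deviation reporting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
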