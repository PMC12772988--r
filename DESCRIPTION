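Package: respirate
Title: Contactless Respiratory Rate Estimation from Breathing Audio and Chest-Motion Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates respiratory rate (breaths per minute) from contactless
    recordings: log-Mel spectrograms of breathing audio and grid-averaged
    intensity features of chest-motion video. Implements an autocorrelation
    estimator over periodicity-ranked feature channels with a breathing-interval
    prior, a recurrent (BLSTM) framewise breathing-boundary detector, and a
    hidden semi-Markov model Viterbi decoder that aligns individual breaths and
    reads the rate off the mean inter-breath interval. Includes a synthetic
    generator for boundary-annotated breathing audio, periodic video grid
    features and SNR-controlled noise mixtures, plus an evaluation harness
    (MAE, Bland-Altman, noise-robustness sweeps) and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    EBImage,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    pROC
Config/testthat/edition: 3
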