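Package: handwashr
Title: Gesture Recognition for WHO Hand-Hygiene Training from Dual-Armband
    EMG and IMU Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A complete signal-processing chain for recognising the nine
    gestures of the WHO hand-hygiene routine from two forearm armbands, each
    streaming 8-channel surface electromyography (200 Hz, int8) and a
    10-channel inertial measurement unit (50 Hz). The chain covers Daubechies
    wavelet log-energy feature extraction with feature-level alignment of the
    EMG to the IMU frame rate, a one-vs-all ensemble of feed-forward neural
    networks trained by scaled conjugate gradient with cross-entropy, and a
    left-to-right chain hidden Markov model whose Viterbi decoding smooths the
    per-frame predictions into a routine-consistent gesture sequence.
    Includes a synthetic dual-armband cohort generator emulating a
    multi-subject acquisition protocol (with between-repetition armband
    placement perturbation), subject-wise k-fold cross-validation, confusion
    matrices, hyperparameter sweep helpers, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
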