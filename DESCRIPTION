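Package: eegcurate
Title: Data-Centric Curation and Evaluation for EEG Emotion Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A data-centric pipeline for EEG-based emotion recognition:
    participant-score-guided noise filtering, label-preserving data
    augmentation (same-class averaging, Gaussian feature noise, cross-participant
    time-domain averaging), differential-entropy band features, small
    one-dimensional convolutional network classifiers, and a leakage-safe
    five-fold cross-validation and reporting harness. Includes a seeded
    generator for SEED-VII-shaped synthetic corpora with a controllable
    low-confidence subpopulation, so cleaning and augmentation effects are
    recoverable without access to the registration-gated dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
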