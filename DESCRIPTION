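Package: p300lbp
Title: Single-Trial P300 Detection from Symbolized EEG with an Autoencoded 1D-CNN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for single-trial detection of the P300 event-related
    potential in odd-ball brain-computer interfaces. Provides a synthetic
    odd-ball EEG session generator with known ground truth, a preprocessing
    chain (zero-phase band-pass filtering, trial epoching, local baseline
    correction, winsorizing, one-dimensional local binary pattern
    symbolization), a compact autoencoded one-dimensional convolutional
    neural network classifier with two-phase training and a per-layer
    parameter/MACC complexity ledger, imbalance-aware resampling
    (NearMiss-2 undersampling plus random oversampling), recursive backward
    channel elimination, paradigm-level decision aggregation for four-choice
    and 6x6 speller protocols, and BCI performance analytics (precision,
    recall, accuracy, F1, information transfer rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
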