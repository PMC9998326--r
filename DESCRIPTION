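Package: premove
Title: Single-Trial EEG Decoding of Upcoming Hand Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A signal-processing and classification pipeline for predicting
    which hand (left or right) a person will use for a reaching movement from
    a short window of multichannel EEG around visual-stimulus onset. Provides
    causally-clean preprocessing (zero-phase FIR filtering, epoching,
    pre-stimulus-only artifact rejection and ICA cleaning, EMG movement-onset
    detection), two feature backends (independent-component mean/variance
    features with evoked subtraction, and spatiotemporal PCA), regularized
    logistic-regression classification with a cross-validated lambda grid,
    parameter-optimization procedures (time-window grid search, greedy channel
    selection with point-based group ranking, learning curves), a strictly
    causal real-time simulation mode, and neurophysiological interpretation
    outputs (classifier topography, Morlet time-frequency class contrasts,
    minimum-norm source projection). A synthetic-session generator with known
    ground truth makes every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
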