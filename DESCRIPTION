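Package: equibeat
Title: Equine and Human ECG Beat Detection and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for beat-to-beat analysis of equine and
    human electrocardiograms. Provides a parametric two-lead ECG simulator
    with known beat annotations, WFDB record reading with beat-class
    remapping and resampling to a common 500 Hz rate, baseline-wander
    removal by cascaded median filters, wavelet-threshold denoising,
    S-peak detection from squared stationary-wavelet detail coefficients
    with an adaptive rolling-mean threshold and refractory rule, a
    Pan-Tompkins reference detector, classifier dataset construction
    (two-lead morphology windows plus binary beat-timing vectors) with
    median class resampling, a parallel convolutional neural network that
    fuses beat morphology and beat timing (with transfer learning and
    majority-vote ensembling), NSGA-II hyperparameter search over the
    network architecture, and standard per-class evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
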