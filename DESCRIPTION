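Package: apneaCNN
Title: Sleep Apnea Screening from Single-Lead ECG with a 1D Deep
    Convolutional Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Per-minute detection of sleep apnea events from single-lead
    electrocardiogram recordings sampled at 100 Hz, and per-recording
    obstructive sleep apnea (OSA) screening via the estimated
    apnea-hypopnea index (AHI). Provides readers and writers for
    WFDB-style signal and minute-annotation files (with a plain CSV
    fallback), Butterworth bandpass preprocessing with per-minute
    z-score standardization, a configurable 1D deep convolutional
    neural network classifier implemented natively in R (convolution
    via im2col and BLAS, batch normalization, max pooling, dropout,
    softmax cross-entropy, Adam optimization, He-normal
    initialization), analytic layer-shape and parameter arithmetic,
    training with best-validation checkpointing and repeated
    experiments, confusion-matrix / ROC / AUC evaluation, AHI-based
    per-recording diagnosis, and a deterministic synthetic ECG
    generator with planted per-minute apnea labels so the whole
    pipeline is testable without any physiological recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
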