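Package: rhythmnet
Title: Atrial Fibrillation Detection from Single-Lead ECG with a 1D
    Convolutional Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for screening single-lead ECG recordings
    for atrial fibrillation across heterogeneous sampling frequencies
    (100-500 Hz). Provides a seeded synthetic ECG rhythm generator
    (normal sinus, atrial fibrillation, and other arrhythmias), discrete
    wavelet transform denoising with the Sym5 mother wavelet, fixed-length
    2700-sample episode segmentation with tail zero-padding, a declarative
    13-convolution/5-max-pooling one-dimensional convolutional neural
    network with exact per-layer shape and parameter accounting, a
    class-weighted k-fold training protocol with inter- and intra-patient
    splitting, five-metric evaluation (accuracy, sensitivity, specificity,
    precision, F1), and a command-line interface. Reads and writes plain
    CSV records and WFDB-format record/annotation pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
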