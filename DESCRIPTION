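Package: ccdnet
Title: Chest-Compression-Depth Quality Classification from Accelerometer Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates, filters and segments chest-compression accelerometry and
    classifies each compression pulse as correct-depth (5-6 cm) or abnormal with
    small one-dimensional convolutional neural networks. Provides dual
    sliding-window pulse recognition with amplitude-controlled low-pass and
    median filtering, max-value alignment of cut pulses to a fixed-length
    network input, pure-R 1D-CNN architectures (a LeNet5 adaptation and the
    deeper CPCNN variants) with batch normalization, dropout and Adam training,
    evaluation metrics (accuracy, F-score, ROC/AUC), and the traditional
    double-integration depth estimate as a baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
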