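Package: becg
Title: Near-Lossless ECG Compression with a Binary Convolutional
    Autoencoder and Residual Error Compensation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compresses single-lead electrocardiogram (ECG) recordings at a
    fixed 117.33:1 ratio by encoding each 320-sample heartbeat into a 20-bit
    binary code with a binary convolutional autoencoder (BCAE) and packaging
    it with a 10-bit inter-beat interval code into a 30-bit unit. A residual
    error compensation network (RECN) predicts a magnified reconstruction
    residual from the binary code and refines the decoded beat. Includes
    bandpass filtering and max-min normalization, Pan-Tompkins R-peak
    detection, fixed-window beat segmentation, bit-exact stream packaging,
    record stitching, training of both networks with a pseudo-Huber loss and
    Adagrad, the standard reconstruction metrics (CR, SNR, RMS, PRD, PRDN,
    QS), a seedable synthetic ECG generator for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
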