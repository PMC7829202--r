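Package: abrwave
Title: Automatic Recognition of Auditory Brainstem Response Characteristic Waves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting the characteristic waves (I, III and V) of
    click-evoked auditory brainstem response (ABR) recordings. Provides a
    synthetic ABR simulator with ground-truth annotations, the canonical
    1,024-point acquisition grid and plain-text data formats, binary
    per-sample label construction with label-area dilation, discrete-wavelet
    denoising, a bidirectional LSTM per-sample sequence classifier trained
    with per-step cross-entropy (implemented in C++ with analytic gradients),
    run-merging postprocessing that converts per-sample probabilities into
    wave latencies, and tolerance-window accuracy metrics with repeated
    k-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
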