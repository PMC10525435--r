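Package: transrr
Title: Transformer-Based Respiratory Rate Estimation from ECG and PPG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates respiratory rate (breaths per minute) from
    simultaneous electrocardiogram and photoplethysmogram recordings with
    TransRR, a Transformer-encoder regression model augmented with kernel-
    and dilation-inception convolution blocks. Provides the full signal
    conditioning pipeline (respiratory band-pass filtering, variational
    mode decomposition denoising, per-subject normalization, windowing),
    the training protocol with plateau learning-rate scheduling and early
    stopping, an evaluation suite (mean absolute error, percentage error,
    Pearson correlation, Bland-Altman limits of agreement), a subject-level
    k-fold cross-validation harness that guards against subject leakage,
    a synthetic respiratory-modulated signal generator with exact ground
    truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
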