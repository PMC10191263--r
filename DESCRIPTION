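Package: popstrf
Title: Population Spectro-Temporal Encoding Models for Auditory Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and evaluates a family of spectro-temporal encoding models
    that predict time-varying firing rates of auditory cortical neurons from
    sound spectrograms: rank-factorized linear-nonlinear (LN) models,
    single-neuron convolutional models, and population convolutional models
    with a shared core and per-neuron readouts. Includes a fixed gammatone
    log-spectrogram frontend, two-stage multi-initialization gradient fitting
    with early stopping, noise-ceiling-corrected prediction correlation
    (trial-to-trial response correlation normalization), jackknifed
    significance tests, and generalization protocols (held-out versus matched
    sites, cross-population transfer, SNR-matched subsetting, and data
    subsampling), plus a synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr,
    optparse
Config/testthat/edition: 3
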