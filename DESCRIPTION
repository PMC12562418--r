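Package: spectraseed
Title: Hyperspectral Seed Variety Identification with Residual-Mamba 1D Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for identifying seed varieties from hyperspectral
    imaging data: ENVI-style cube input/output, black/white reflectance
    calibration, automatic seed segmentation and region-of-interest mean
    spectrum extraction, Savitzky-Golay smoothing, stratified splitting,
    PCA/LDA exploratory projections, wavelength selection by the successive
    projections algorithm (SPA) and competitive adaptive reweighted sampling
    (CARS) with partial least squares, and classification with a residual 1D
    convolutional network augmented with selective state-space (Mamba) blocks
    trained under a label-smoothing cross-entropy loss, alongside seven
    reference classifiers and a repeated-run evaluation protocol. Includes a
    synthetic spectra and cube generator emulating 20-class maize seed
    reflectance so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
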