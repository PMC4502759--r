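Package: sevoeeg
Title: Multitaper Spectral and Coherence Analysis of Infant EEG Under
    Sevoflurane Anesthesia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for characterising age-dependent
    electroencephalogram (EEG) dynamics in infants under sevoflurane general
    anesthesia: surface-Laplacian re-referencing on a 33-electrode modified
    10/20 montage, anti-alias filtering and downsampling, multitaper
    spectrograms and group-median spectra, frontal (F7-F8) coherograms,
    global coherence via eigendecomposition of the median-denoised
    cross-spectral matrix, frequency-domain bootstrap confidence intervals
    for group and paired spectral differences, and end-tidal-concentration
    binned emergence analysis. Includes a seeded synthetic infant-EEG cohort
    generator with age-dependent oscillator templates so the full pipeline is
    testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deldir,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    matrixStats,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
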