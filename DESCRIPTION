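Package: hsisort
Title: Online Near-Infrared Hyperspectral Imaging Pipeline for Seed
    Viability Sorting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end chemometrics pipeline for line-scan near-infrared
    hyperspectral imaging (900-1700 nm) of seeds: two-point reflectance
    calibration against white/dark references, spatial median filtering,
    threshold segmentation with area opening, per-seed mean-spectrum
    extraction, a suite of spectral preprocessing transforms (mean/max/range
    normalisation, MSC, SNV, Savitzky-Golay derivatives), a NIPALS PLS-DA
    viability classifier with cross-validated latent-variable selection and
    purity-driven decision-threshold shifting, pixel-wise chemical imaging,
    a streaming online-sorting emulation with exact streaming/batch
    equivalence, and downstream verification statistics (moisture content,
    one-way ANOVA, germination-rate accounting). Includes a synthetic scene
    generator with full ground truth so every stage is testable.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
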