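Package: ovofresh
Title: Visible-NIR Chemometrics for Shell-Egg Freshness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Chemometric analysis of shell-egg freshness from visible and
    near-infrared diffuse-transmittance spectra. Computes the classical
    destructive freshness indices (Haugh unit, yolk index, weight-loss rate)
    and their storage-time summaries, provides leakage-free spectral
    pretreatments (standard normal variate, multiplicative scatter
    correction, Savitzky-Golay derivatives), qualitative storage-day
    discrimination by linear discriminant analysis on principal-component
    scores, and quantitative calibration by synergy-interval partial least
    squares (Si-PLS) with leave-one-out cross-validated wavelength-interval
    selection. A synthetic spectra generator emulating two storage regimes
    (room temperature and refrigerated) supplies ground truth for every
    pipeline stage.
License: MIT
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
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
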