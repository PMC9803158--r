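Package: lassa
Title: Heart Rate from Remote Photoplethysmography via Low-Rank and
    Autocorrelation Guided Singular Spectrum Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Denoises camera-based photoplethysmography (rPPG) traces and
    extracts heart rate.  The trace is embedded in a Hankel trajectory
    matrix and decomposed by singular value decomposition; the number of
    components kept is set globally by the rank of the low-rank part of an
    exact augmented-Lagrange-multiplier robust PCA split of the trajectory
    matrix, and the retained components are screened locally by their
    maximum autocorrelation peak before singular-value-weighted
    reconstruction.  Includes the full preprocessing chain
    (smoothness-prior detrending, normalization, moving-average smoothing,
    ensemble empirical mode decomposition with spectral mode selection),
    windowed FFT heart-rate readout, agreement metrics (MAE, RMSE, Pearson
    r, Bland-Altman limits), an RGB+hue skin-pixel classifier for region
    -of-interest reduction, and synthetic pulse/image generators for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
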