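Package: fluorspec
Title: Estimating Leaf Photosynthetic and Chlorophyll-Fluorescence Parameters
    from Hyperspectral Reflectance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A chemometrics pipeline for estimating chlorophyll fluorescence and
    photosynthetic gas-exchange (CFPGE) parameters of salinity-stressed leaves
    from 350-2500 nm reflectance spectra. Provides continuous wavelet transform
    (Gaus1, dyadic scales 2^1-2^10) and standard normal variate preprocessing,
    successive projections algorithm (SPA) wavelength selection under
    spectral-region constraints, partial least squares (SIMPLS) and RBF
    support-vector regression calibration, and R2/RMSE/RPD model evaluation.
    Includes a synthetic leaf-spectra generator that emulates the salinity
    dose-response structure of the target system so the full pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite,
    yaml,
    data.table,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'SpectraSet-methods.R'
    'evaluation.R'
    'feature-selection.R'
    'fluorescence.R'
    'io.R'
    'modeling.R'
    'preprocessing.R'
    'synthetic-params.R'
    'synthetic-spectra.R'
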