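#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' Canonical 1-nm wavelength grid (350--2500 nm, 2151 bands)
#'
#' All spectra handled by the package live on this grid; raw instrument
#' wavelengths are interpolated onto it with [resampleToGrid()].
#'
#' @return Integer vector of 2151 wavelengths in nanometres.
#' @export
#' @examples
#' length(canonicalGrid())
canonicalGrid <- function() 350:2500

#' The ten CFPGE target parameters
#'
#' Column names used throughout for the chlorophyll fluorescence and
#' photosynthetic gas-exchange (CFPGE) parameters: net photosynthetic rate
#' (Pn), transpiration rate (Tr), stomatal conductance (gs), intercellular
#' CO2 concentration (Ci), actual PSII photochemical efficiency (PhiPSII),
#' maximum PSII photochemical efficiency (FvFm), potential PSII activity
#' (FvF0), photochemical quenching (qP), non-photochemical quenching (NPQ)
#' and apparent electron transport rate (ETR).
#'
#' @return Character vector of length 10.
#' @export
cfpgeParameterNames <- function() {
  c("Pn", "Tr", "gs", "Ci", "PhiPSII", "FvFm", "FvF0", "qP", "NPQ", "ETR")
}

#' SpectraSet: leaf spectra with paired CFPGE parameters
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' bands-by-samples matrix in the `"spectra"` assay. `rowData` carries the
#' wavelength of every band (`wavelength_nm`); `colData` carries per-sample
#' metadata: salinity group, day, the ten CFPGE parameters and, for generated
#' data, the raw fluorescence yields they derive from.
#'
#' @slot preprocessing character scalar describing the transform history of
#'   the assay (`"reflectance"`, `"snv"`, or `"cwt"` in the [WaveletSet]
#'   subclass).
#' @export
setClass("SpectraSet",
  contains = "SummarizedExperiment",
  representation(preprocessing = "character"),
  prototype(preprocessing = "reflectance")
)

setValidity("SpectraSet", function(object) {
  msg <- NULL
  if (!"spectra" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'spectra' is missing")
  wl <- SummarizedExperiment::rowData(object)$wavelength_nm
  if (is.null(wl))
    msg <- c(msg, "rowData must contain 'wavelength_nm'")
  else {
    if (anyNA(wl) || is.unsorted(wl, strictly = TRUE))
      msg <- c(msg, "wavelengths must be strictly increasing")
  }
  if (is.null(msg)) TRUE else msg
})

#' WaveletSet: continuous wavelet coefficients of a SpectraSet
#'
#' Holds the Gaus1 CWT coefficient matrix at one dyadic scale. The scale is
#' `2^scaleIndex` bands; `rowData(x)$edge_affected` flags bands whose
#' coefficients fall inside the reflect-padding influence zone at the grid
#' boundaries.
#'
#' @slot scaleIndex integer in 1..10; the decomposition scale is `2^scaleIndex`.
#' @export
setClass("WaveletSet",
  contains = "SpectraSet",
  representation(scaleIndex = "integer"),
  prototype(preprocessing = "cwt", scaleIndex = 1L)
)

setValidity("WaveletSet", function(object) {
  if (length(object@scaleIndex) != 1L || is.na(object@scaleIndex))
    return("scaleIndex must be a single integer")
  if (is.null(SummarizedExperiment::rowData(object)$edge_affected))
    return("rowData must contain 'edge_affected'")
  TRUE
})

#' FeatureSelection: an SPA wavelength-selection result
#'
#' @slot wavelengths numeric, selected wavelengths (nm) in SPA chain order.
#' @slot selectionOrder integer ranks 1..k of the chain.
#' @slot regionLabels character, spectral region of each wavelength
#'   (`blue_green`, `red`, `nir`).
#' @slot rmseCurve numeric, validation RMSE of the OLS calibration model for
#'   chain prefixes of size 1..maxVars (for the winning start column).
#' @slot chosenSize integer, prefix size minimising validation RMSE.
#' @slot startWavelength numeric, wavelength of the winning chain start.
#' @slot maxAbsCorrelation numeric, largest pairwise |r| among selected
#'   columns on the calibration set (collinearity diagnostic).
#' @slot parameter character, name of the response the selection was run for.
#' @export
setClass("FeatureSelection",
  representation(
    wavelengths = "numeric",
    selectionOrder = "integer",
    regionLabels = "character",
    rmseCurve = "numeric",
    chosenSize = "integer",
    startWavelength = "numeric",
    maxAbsCorrelation = "numeric",
    parameter = "character"
  )
)

setValidity("FeatureSelection", function(object) {
  msg <- NULL
  if (anyDuplicated(object@wavelengths))
    msg <- c(msg, "selected wavelengths must be unique")
  if (length(object@wavelengths) != object@chosenSize)
    msg <- c(msg, "chosenSize must equal the number of selected wavelengths")
  if (length(object@regionLabels) != length(object@wavelengths))
    msg <- c(msg, "one region label per wavelength required")
  if (is.null(msg)) TRUE else msg
})

#' DataSplit: stratified calibration/validation partition
#'
#' @slot calibration integer sample indices of the calibration (modelling) set.
#' @slot validation integer sample indices of the validation set.
#' @slot removed integer indices eliminated by the outlier rule.
#' @slot seed integer seed the split was drawn with.
#' @export
setClass("DataSplit",
  representation(
    calibration = "integer",
    validation = "integer",
    removed = "integer",
    seed = "integer"
  )
)

setValidity("DataSplit", function(object) {
  if (length(intersect(object@calibration, object@validation)) > 0)
    return("calibration and validation sets must be disjoint")
  TRUE
})

#' PLSRModel: a SIMPLS partial least squares regression model
#'
#' @slot coefficients numeric, regression coefficients on the original
#'   (centred) predictor scale for the chosen number of latent variables.
#' @slot intercept numeric scalar.
#' @slot nLV integer, chosen number of latent variables.
#' @slot weights,loadings matrices of SIMPLS weight and loading vectors
#'   (columns = latent variables, up to `maxLV`).
#' @slot yLoadings numeric, y-loadings per latent variable.
#' @slot xMeans,xScales,yMean centring/scaling applied before fitting.
#' @slot rmsecv numeric, cross-validated RMSE per candidate LV count.
#' @slot featureWavelengths numeric, wavelengths of the predictor columns.
#' @slot parameter character, response name.
#' @slot provenance list, preprocessing provenance (scale index, snv flag, ...).
#' @export
setClass("PLSRModel",
  representation(
    coefficients = "numeric",
    intercept = "numeric",
    nLV = "integer",
    weights = "matrix",
    loadings = "matrix",
    yLoadings = "numeric",
    xMeans = "numeric",
    xScales = "numeric",
    yMean = "numeric",
    rmsecv = "numeric",
    featureWavelengths = "numeric",
    parameter = "character",
    provenance = "list"
  )
)

#' SVRModel: an RBF-kernel epsilon support vector regression model
#'
#' Wraps an [e1071::svm] fit together with the Monte-Carlo cross-validation
#' grid search over the penalty `c` and kernel width `g`.
#'
#' @slot fit the underlying `e1071::svm` object (trained on standardised data).
#' @slot cost,gamma,epsilon chosen hyperparameters.
#' @slot gridRMSE matrix of mean hold-out RMSE over the (c, g) grid
#'   (rows = c values, columns = g values).
#' @slot cvRMSE numeric, mean hold-out RMSE at the chosen grid point (used as
#'   the RMSECV entering RPD).
#' @slot xMeans,xScales,yMean,yScale standardisation applied before fitting.
#' @slot featureWavelengths numeric, wavelengths of the predictor columns.
#' @slot parameter character, response name.
#' @slot provenance list, preprocessing provenance.
#' @export
setClass("SVRModel",
  representation(
    fit = "ANY",
    cost = "numeric",
    gamma = "numeric",
    epsilon = "numeric",
    gridRMSE = "matrix",
    cvRMSE = "numeric",
    xMeans = "numeric",
    xScales = "numeric",
    yMean = "numeric",
    yScale = "numeric",
    featureWavelengths = "numeric",
    parameter = "character",
    provenance = "list"
  )
)
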