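#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a SpectraSet
#'
#' @param spectra numeric samples-by-bands matrix (chemometrics orientation);
#'   it is stored transposed, bands-by-samples, in the assay.
#' @param wavelengths numeric vector of band wavelengths (nm), strictly
#'   increasing; defaults to the canonical 350--2500 nm grid.
#' @param sampleData `data.frame` (or DataFrame) of per-sample metadata,
#'   typically the CFPGE parameter table; one row per spectrum.
#' @param preprocessing character label of the assay state.
#' @return A [SpectraSet].
#' @export
#' @examples
#' m <- matrix(runif(2 * 2151), nrow = 2)
#' ss <- SpectraSet(m)
#' dim(ss)
SpectraSet <- function(spectra, wavelengths = canonicalGrid(),
                       sampleData = NULL, preprocessing = "reflectance") {
  spectra <- as.matrix(spectra)
  if (ncol(spectra) != length(wavelengths))
    stop("spectra must have one column per wavelength (got ", ncol(spectra),
         " columns for ", length(wavelengths), " wavelengths)")
  n <- nrow(spectra)
  if (is.null(sampleData)) {
    sampleData <- S4Vectors::DataFrame(row.names = sprintf("sample_%03d", seq_len(n)))
  } else {
    sampleData <- S4Vectors::DataFrame(sampleData)
    if (nrow(sampleData) != n)
      stop("sampleData must have one row per spectrum")
    if (is.null(rownames(sampleData)))
      rownames(sampleData) <- sprintf("sample_%03d", seq_len(n))
  }
  assay <- t(spectra)
  dimnames(assay) <- list(as.character(wavelengths), rownames(sampleData))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(spectra = assay),
    rowData = S4Vectors::DataFrame(wavelength_nm = as.numeric(wavelengths)),
    colData = sampleData
  )
  new("SpectraSet", se, preprocessing = preprocessing)
}

#' @describeIn SpectraSet samples-by-bands matrix accessor.
#' @param x a `SpectraSet`.
#' @export
setMethod("spectraMatrix", "SpectraSet", function(x) {
  t(SummarizedExperiment::assay(x, "spectra"))
})

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectraSet", function(x) {
  as.numeric(SummarizedExperiment::rowData(x)$wavelength_nm)
})

#' @rdname cfpgeTable
#' @export
setMethod("cfpgeTable", "SpectraSet", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' @rdname scaleIndex
#' @export
setMethod("scaleIndex", "WaveletSet", function(x) x@scaleIndex)

#' @rdname edgeAffected
#' @export
setMethod("edgeAffected", "WaveletSet", function(x) {
  as.logical(SummarizedExperiment::rowData(x)$edge_affected)
})

setMethod("show", "SpectraSet", function(object) {
  cat(class(object), "with", ncol(object), "samples x", nrow(object),
      "bands (", object@preprocessing, ")\n")
  wl <- wavelengths(object)
  cat("  wavelengths:", min(wl), "-", max(wl), "nm\n")
  pars <- intersect(cfpgeParameterNames(), colnames(SummarizedExperiment::colData(object)))
  if (length(pars))
    cat("  CFPGE parameters:", paste(pars, collapse = ", "), "\n")
  if (is(object, "WaveletSet"))
    cat("  CWT scale: 2^", object@scaleIndex, " = ", 2^object@scaleIndex,
        " bands; ", sum(edgeAffected(object)), " edge-affected bands\n", sep = "")
})

setMethod("show", "FeatureSelection", function(object) {
  cat("FeatureSelection (", object@parameter, "): ", object@chosenSize,
      " wavelengths, start ", object@startWavelength, " nm\n", sep = "")
  cat("  ", paste(sprintf("%g(%s)", object@wavelengths, object@regionLabels),
                  collapse = " "), "\n")
  cat("  validation RMSE at chosen size:",
      signif(object@rmseCurve[object@chosenSize], 4),
      "; max pairwise |r|:", signif(object@maxAbsCorrelation, 4), "\n")
})

setMethod("show", "DataSplit", function(object) {
  cat("DataSplit: n_c =", length(object@calibration),
      ", n_p =", length(object@validation),
      ", removed =", length(object@removed), "\n")
})

setMethod("show", "PLSRModel", function(object) {
  cat("PLSRModel (", object@parameter, "): ", object@nLV, " latent variables, ",
      length(object@coefficients), " predictors\n", sep = "")
  cat("  RMSECV at chosen LV:", signif(object@rmsecv[object@nLV], 4), "\n")
})

setMethod("show", "SVRModel", function(object) {
  cat("SVRModel (", object@parameter, "): c = ", signif(object@cost, 4),
      ", g = ", signif(object@gamma, 4), ", epsilon = ",
      signif(object@epsilon, 4), "\n", sep = "")
  cat("  MC-CV RMSE:", signif(object@cvRMSE, 4), "\n")
})

#' Calibration/validation accessors for a DataSplit
#'
#' @param split a [DataSplit].
#' @return Integer sample indices.
#' @export
calibrationIndices <- function(split) split@calibration

#' @rdname calibrationIndices
#' @export
validationIndices <- function(split) split@validation

#' Selected wavelengths of a FeatureSelection
#' @param x a [FeatureSelection].
#' @return Numeric vector of wavelengths (nm) in chain order.
#' @export
selectedWavelengths <- function(x) x@wavelengths
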