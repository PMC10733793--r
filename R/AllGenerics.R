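#' @include AllClasses.R
NULL

#' Extract the samples-by-bands spectra matrix
#'
#' Returns the assay of a [SpectraSet] transposed to the chemometrics
#' convention: one row per sample, one column per wavelength, columns named by
#' integer nanometre.
#'
#' @param x a `SpectraSet`.
#' @return Numeric matrix, `n_samples x n_bands`.
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' Wavelength grid of a spectra container
#' @param x a `SpectraSet`.
#' @return Numeric vector of wavelengths (nm), one per band.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' CFPGE parameter table of a spectra container
#' @param x a `SpectraSet`.
#' @return `data.frame` with one row per sample and the ten CFPGE columns
#'   (plus group/day metadata when present).
#' @export
setGeneric("cfpgeTable", function(x) standardGeneric("cfpgeTable"))

#' Dyadic scale index of a wavelet coefficient set
#' @param x a `WaveletSet`.
#' @return Integer `i`; the CWT scale is `2^i` bands.
#' @export
setGeneric("scaleIndex", function(x) standardGeneric("scaleIndex"))

#' Bands whose CWT coefficients are influenced by boundary padding
#' @param x a `WaveletSet`.
#' @return Logical vector, one flag per band.
#' @export
setGeneric("edgeAffected", function(x) standardGeneric("edgeAffected"))

#' Standard normal variate (SNV) transform
#'
#' Centres every spectrum to mean zero and scales it to unit standard
#' deviation (denominator `p - 1`), removing per-sample additive offsets and
#' multiplicative scatter.
#'
#' @param x a `SpectraSet` or a samples-by-bands numeric matrix.
#' @return An object of the same kind with transformed spectra.
#' @export
setGeneric("snvTransform", function(x) standardGeneric("snvTransform"))

#' Continuous wavelet transform (Gaus1) at one dyadic scale
#'
#' @param x a `SpectraSet` or a samples-by-bands numeric matrix.
#' @param scaleIndex integer `i` in 1..10; the scale is `a = 2^i` bands.
#' @param ... passed to methods.
#' @return A [WaveletSet] (or, for a matrix input, a list with `coefficients`
#'   and `edgeAffected`).
#' @export
setGeneric("cwtTransform", function(x, scaleIndex, ...) standardGeneric("cwtTransform"))

#' Continuous wavelet transform at all ten dyadic scales
#' @param x a `SpectraSet` or samples-by-bands matrix.
#' @param ... passed to [cwtTransform()].
#' @return Named list of ten results, `CWT-1` .. `CWT-10`.
#' @export
setGeneric("cwtAllScales", function(x, ...) standardGeneric("cwtAllScales"))
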