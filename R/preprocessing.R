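#' Resample a spectrum onto the canonical 1-nm grid
#'
#' Linear interpolation of instrument samples onto the 350--2500 nm 1-nm
#' grid (2151 bands), endpoints inclusive.
#'
#' @param rawWavelengths strictly increasing wavelengths (nm) covering
#'   the full target range.
#' @param rawValues reflectance values, same length.
#' @param grid target grid (default [canonicalGrid()]).
#' @return Numeric vector on `grid`.
#' @export
#' @examples
#' r <- resampleToGrid(c(350, 2500), c(0.1, 0.5))
#' length(r)
resampleToGrid <- function(rawWavelengths, rawValues, grid = canonicalGrid()) {
  if (length(rawWavelengths) != length(rawValues))
    stop("wavelengths and values must have equal length")
  if (is.unsorted(rawWavelengths, strictly = TRUE))
    stop("raw wavelengths must be strictly increasing")
  if (min(rawWavelengths) > min(grid) || max(rawWavelengths) < max(grid))
    stop("raw wavelengths do not cover the target range ",
         min(grid), "-", max(grid), " nm")
  stats::approx(rawWavelengths, rawValues, xout = grid, method = "linear")$y
}

#' Average replicate spectra
#'
#' Per-band arithmetic mean of replicate measurements of the same leaf
#' (e.g. left/middle/right clip positions).
#'
#' @param spectra numeric matrix with one replicate per row, or a list of
#'   equal-length numeric vectors.
#' @return Numeric vector, the per-band mean.
#' @export
averageReplicates <- function(spectra) {
  if (is.list(spectra)) {
    len <- lengths(spectra)
    if (length(unique(len)) != 1)
      stop("replicate spectra are on mismatched grids")
    spectra <- do.call(rbind, spectra)
  }
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 1) stop("at least one replicate spectrum required")
  colMeans(spectra)
}

#' @rdname snvTransform
#' @export
setMethod("snvTransform", "matrix", function(x) {
  p <- ncol(x)
  if (p < 2) stop("SNV requires at least 2 bands per spectrum")
  mu <- rowMeans(x)
  centred <- x - mu
  s <- sqrt(rowSums(centred^2) / (p - 1))
  bad <- which(s < .Machine$double.eps * 100)
  if (length(bad)) {
    nm <- if (!is.null(rownames(x))) rownames(x)[bad[1]] else bad[1]
    stop("zero-variance spectrum cannot be SNV-transformed (sample ", nm, ")")
  }
  centred / s
})

#' @rdname snvTransform
#' @export
setMethod("snvTransform", "SpectraSet", function(x) {
  out <- snvTransform(spectraMatrix(x))
  SpectraSet(out, wavelengths(x),
             sampleData = SummarizedExperiment::colData(x),
             preprocessing = "snv")
})

# Discretised Gaus1 (first derivative of a Gaussian) wavelet, L2-normalised.
# Truncated at +/- 8a: the neglected tail mass (~exp(-32)) is ~1e-14, so the
# discrete correlation matches untruncated quadrature well below 1e-6 even
# where fine-scale coefficients of smooth spectra are small.
gaus1Kernel <- function(scale) {
  L <- ceiling(8 * scale)
  u <- (-L:L) / scale
  list(values = -u * exp(-u^2 / 2) / sqrt(scale), halfSupport = L)
}

# CWT of a samples x bands matrix at one scale: correlation of each spectrum
# with the dilated/translated wavelet, symmetric (reflect) padding to half
# the wavelet support. Returns coefficients plus the edge-influence flags.
.cwtMatrix <- function(x, scaleIndex, override = FALSE) {
  if (!(scaleIndex %in% 1:10) && !override)
    stop("scaleIndex must be in 1..10 (use override = TRUE to force)")
  p <- ncol(x)
  a <- 2^scaleIndex
  k <- gaus1Kernel(a)
  L <- k$halfSupport
  # symmetric (reflect) padding without repeating the edge sample; the
  # triangular-wave index handles pad lengths exceeding the grid
  idx <- (1 - L):(p + L)
  q <- (idx - 1) %% (2 * p - 2)
  padIdx <- ifelse(q <= p - 1, q + 1, 2 * p - 1 - q)
  edge <- seq_len(p) <= L | seq_len(p) > p - L
  if (nrow(x) == 0)
    return(list(coefficients = matrix(0, 0, p), edgeAffected = edge,
                scaleIndex = as.integer(scaleIndex)))
  # batched linear convolution via power-of-two FFTs:
  # coef[s, b] = sum_t x[s, t] * psi((t - b)/a) with reflect-padded t.
  # The kernel is real, so two spectra ride one complex FFT
  # (conv(x1 + i*x2) = conv(x1) + i*conv(x2)); N >= P suffices because the
  # circular wrap only touches output positions outside the valid region.
  P <- p + 2 * L
  N <- stats::nextn(P, c(2, 3))
  kpad <- complex(real = c(rev(k$values), numeric(N - 2 * L - 1)))
  FK <- stats::fft(kpad)
  n <- nrow(x)
  coef <- matrix(0, n, p)
  valid <- (2 * L + 1):(2 * L + p)
  chunk <- 128L  # spectra per FFT batch (two per complex column)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    idx1 <- seq(lo, hi, by = 2L)
    idx2 <- idx1 + 1L
    hasIm <- idx2 <= hi
    A <- matrix(complex(real = 0), N, length(idx1))
    A[seq_len(P), ] <- t(x[idx1, padIdx, drop = FALSE])
    A[seq_len(P), hasIm] <- A[seq_len(P), hasIm, drop = FALSE] +
      (0 + 1i) * t(x[idx2[hasIm], padIdx, drop = FALSE])
    Z <- stats::mvfft(stats::mvfft(A) * FK, inverse = TRUE) / N
    coef[idx1, ] <- t(Re(Z[valid, , drop = FALSE]))
    coef[idx2[hasIm], ] <- t(Im(Z[valid, hasIm, drop = FALSE]))
  }
  list(coefficients = coef, edgeAffected = edge, scaleIndex = as.integer(scaleIndex))
}

#' @rdname cwtTransform
#' @param override allow scale indices outside 1..10.
#' @export
setMethod("cwtTransform", "matrix", function(x, scaleIndex, override = FALSE) {
  .cwtMatrix(x, scaleIndex, override)
})

#' @rdname cwtTransform
#' @export
setMethod("cwtTransform", "SpectraSet", function(x, scaleIndex, override = FALSE) {
  res <- .cwtMatrix(spectraMatrix(x), scaleIndex, override)
  assay <- t(res$coefficients)
  dimnames(assay) <- dimnames(SummarizedExperiment::assay(x, "spectra"))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(spectra = assay),
    rowData = S4Vectors::DataFrame(wavelength_nm = wavelengths(x),
                                   edge_affected = res$edgeAffected),
    colData = SummarizedExperiment::colData(x)
  )
  new("WaveletSet", se, preprocessing = "cwt",
      scaleIndex = res$scaleIndex)
})

#' @rdname cwtAllScales
#' @export
setMethod("cwtAllScales", "matrix", function(x, ...) {
  out <- lapply(1:10, function(i) cwtTransform(x, i, ...))
  names(out) <- paste0("CWT-", 1:10)
  out
})

#' @rdname cwtAllScales
#' @export
setMethod("cwtAllScales", "SpectraSet", function(x, ...) {
  out <- lapply(1:10, function(i) cwtTransform(x, i, ...))
  names(out) <- paste0("CWT-", 1:10)
  out
})
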