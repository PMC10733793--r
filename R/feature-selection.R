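#' @useDynLib fluorspec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Spectral region definitions
#'
#' The three regions used for feature-set construction: blue-green
#' \[350, 600) nm, red \[600, 800\] nm and near-infrared (800, 2500\] nm.
#'
#' @return `data.frame` with columns `name`, `low`, `high`,
#'   `lowInclusive`, `highInclusive`.
#' @export
spectralRegions <- function() {
  data.frame(
    name = c("blue_green", "red", "nir"),
    low = c(350, 600, 800),
    high = c(600, 800, 2500),
    lowInclusive = c(TRUE, TRUE, FALSE),
    highInclusive = c(FALSE, TRUE, TRUE)
  )
}

#' Band mask for a set of spectral regions
#'
#' A band is included iff it falls inside any listed region. `regionMask(grid,
#' "red")` gives the red-only (RSF) candidate set; all three regions give the
#' full-spectrum (FSF) set, i.e. every band.
#'
#' @param grid wavelength grid (nm).
#' @param regions character vector of region names (see [spectralRegions()]);
#'   may be empty.
#' @return Logical vector over `grid`.
#' @export
#' @examples
#' sum(regionMask(canonicalGrid(), "red")) # 201 bands
regionMask <- function(grid, regions) {
  tab <- spectralRegions()
  unknown <- setdiff(regions, tab$name)
  if (length(unknown))
    stop("unknown region name(s): ", paste(unknown, collapse = ", "))
  mask <- rep(FALSE, length(grid))
  for (r in regions) {
    row <- tab[tab$name == r, ]
    lo <- if (row$lowInclusive) grid >= row$low else grid > row$low
    hi <- if (row$highInclusive) grid <= row$high else grid < row$high
    mask <- mask | (lo & hi)
  }
  mask
}

#' Region label of each wavelength
#' @param wl wavelengths (nm).
#' @return Character vector (`blue_green`, `red`, `nir`).
#' @export
regionOf <- function(wl) {
  out <- character(length(wl))
  for (r in spectralRegions()$name)
    out[regionMask(wl, r)] <- r
  out
}

#' SPA projection chain from one start column
#'
#' Iteratively projects all unselected columns onto the orthogonal complement
#' of the span of the selected columns and appends the column of maximal
#' residual norm (greedy Gram-Schmidt pivoting). Columns are centred before
#' projection. The chain truncates, with a warning, when the remaining
#' residual norms fall below `tol` times the largest column norm (exactly
#' collinear remainder).
#'
#' @param X numeric matrix (samples x candidate columns).
#' @param start index of the start column.
#' @param k chain length requested.
#' @param tol relative tolerance for a "zero" residual norm (default 1e-10).
#' @return Integer vector of column indices in selection order.
#' @export
spaChain <- function(X, start, k, tol = 1e-10) {
  X <- as.matrix(X)
  if (start < 1 || start > ncol(X)) stop("start column out of range")
  if (k < 1) stop("k must be >= 1")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  absTol <- tol * sqrt(max(colSums(Xc^2)))
  k <- min(k, nrow(X) - 1, ncol(X))
  out <- .spaChainCpp(Xc, as.integer(start), as.integer(k), absTol)
  if (length(out) < k)
    warning("SPA chain truncated at ", length(out),
            " columns: remaining columns are collinear with the selection")
  out
}

#' SPA wavelength selection with validation-RMSE subset sizing
#'
#' Runs an SPA chain from every candidate start column inside the region
#' mask; for each chain prefix of size 1..`maxVars` an ordinary
#' least-squares calibration model is fitted on the calibration set and its
#' RMSE on the validation set recorded. The (start, size) pair minimising
#' validation RMSE wins; ties break to the smaller subset, then the lower
#' start wavelength. Columns are centred on the calibration set before
#' projection but, as in classic SPA, not variance-scaled: the projection
#' chain deliberately exploits column variance to seek informative bands,
#' and the pipeline always runs the selection within a single preprocessing
#' (one wavelet scale), where coefficient magnitudes are homogeneous. Set
#' `scale = TRUE` to autoscale if mixing matrices of unlike units.
#'
#' @param X numeric samples-by-bands matrix (reflectance or wavelet
#'   coefficients).
#' @param y response vector (one CFPGE parameter).
#' @param split a [DataSplit] giving calibration/validation rows.
#' @param wavelengths band wavelengths (nm), one per column of `X`.
#' @param mask logical candidate-band mask (default: all bands).
#' @param maxVars largest subset size considered (default 30).
#' @param tol relative zero-residual tolerance (default 1e-10).
#' @param scale also scale candidate columns to unit calibration variance
#'   (default FALSE, centring only).
#' @param parameter response name stored in the result.
#' @return A [FeatureSelection].
#' @export
spaSelect <- function(X, y, split, wavelengths = canonicalGrid(),
                      mask = NULL, maxVars = 30, tol = 1e-10, scale = FALSE,
                      parameter = "y") {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("y must have one value per row of X")
  if (is.null(mask)) mask <- rep(TRUE, ncol(X))
  if (length(mask) != ncol(X)) stop("mask must have one flag per band")
  if (maxVars < 1) stop("maxVars must be >= 1")
  cal <- split@calibration
  val <- split@validation
  ycal <- y[cal]
  if (stats::sd(ycal) < .Machine$double.eps * 100)
    stop("degenerate response: zero variance on the calibration set")

  cols <- which(mask)
  Xcal <- X[cal, cols, drop = FALSE]
  mu <- colMeans(Xcal)
  sdev <- apply(Xcal, 2, stats::sd)
  usable <- sdev > 1e-12
  cols <- cols[usable]
  mu <- mu[usable]
  sdev <- if (scale) sdev[usable] else rep(1, length(cols))
  Xcal <- base::scale(X[cal, cols, drop = FALSE], center = mu, scale = sdev)
  Xval <- base::scale(X[val, cols, drop = FALSE], center = mu, scale = sdev)
  absTol <- tol * sqrt(max(colSums(Xcal^2)))

  res <- .spaScanCpp(Xcal, ycal - mean(ycal), mean(ycal), Xval, y[val],
                     as.integer(maxVars), absTol)
  chosen <- res$chain[seq_len(res$size)]
  wl <- wavelengths[cols[chosen]]
  maxCor <- if (length(chosen) > 1) {
    cc <- stats::cor(Xcal[, chosen, drop = FALSE])
    max(abs(cc[upper.tri(cc)]))
  } else 0
  new("FeatureSelection",
      wavelengths = wl,
      selectionOrder = seq_along(wl),
      regionLabels = regionOf(wl),
      rmseCurve = as.numeric(res$rmseCurve),
      chosenSize = as.integer(res$size),
      startWavelength = wavelengths[cols[res$start]],
      maxAbsCorrelation = maxCor,
      parameter = parameter)
}
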