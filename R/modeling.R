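#' @importFrom e1071 svm
NULL

# SIMPLS for a univariate response on centred (optionally scaled) data.
# Returns weight/loading arrays and per-component y-loadings; coefficients
# for any number of components are R[, 1:a] %*% q[1:a].
.simpls <- function(Xc, yc, maxLV) {
  n <- nrow(Xc); p <- ncol(Xc)
  A <- min(maxLV, n - 1, p)
  R <- matrix(0, p, A); P <- matrix(0, p, A); V <- matrix(0, p, A)
  q <- numeric(A)
  s <- drop(crossprod(Xc, yc))
  a <- 0
  for (i in seq_len(A)) {
    r <- s
    t <- drop(Xc %*% r)
    tn <- sqrt(sum(t^2))
    if (!is.finite(tn) || tn < 1e-12) break
    t <- t / tn; r <- r / tn
    pv <- drop(crossprod(Xc, t))
    qv <- sum(yc * t)
    v <- pv
    if (a > 0) {
      Va <- V[, seq_len(a), drop = FALSE]
      v <- v - Va %*% crossprod(Va, pv)
    }
    vn <- sqrt(sum(v^2))
    if (vn < 1e-12) break
    v <- v / vn
    s <- s - v * drop(crossprod(v, s))
    a <- i
    R[, i] <- r; P[, i] <- pv; V[, i] <- v; q[i] <- qv
  }
  list(weights = R[, seq_len(a), drop = FALSE],
       loadings = P[, seq_len(a), drop = FALSE],
       yLoadings = q[seq_len(a)], nComp = a)
}

#' Fit a PLSR model (SIMPLS) with cross-validated latent-variable selection
#'
#' Latent variables maximise covariance with the response (SIMPLS
#' deflation). The number of latent variables is chosen to minimise the
#' cross-validated RMSE (RMSECV), with the one-standard-error rule breaking
#' near-ties toward the smaller model.
#'
#' @param X numeric samples-by-features matrix (calibration set).
#' @param y response vector.
#' @param maxLV largest number of latent variables considered (default 10,
#'   capped at the predictor rank bound `min(n-1, p)`).
#' @param cvFolds folds for RMSECV (default 10, capped at n).
#' @param seed seed for the fold assignment.
#' @param scale autoscale predictor columns (default FALSE; centring is
#'   always applied).
#' @param wavelengths feature wavelengths stored in the model.
#' @param parameter response name.
#' @param provenance list recording the preprocessing that produced `X`
#'   (scale index, SNV flag, feature-set label, ...).
#' @return A [PLSRModel].
#' @export
fitPLSR <- function(X, y, maxLV = 10, cvFolds = 10, seed = 1, scale = FALSE,
                    wavelengths = NULL, parameter = "y", provenance = list()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("y must have one value per row of X")
  if (stats::sd(y) < .Machine$double.eps * 100) stop("constant response")
  if (maxLV >= n) stop("maxLV must be below the number of samples")
  maxLV <- min(maxLV, n - 1, ncol(X))

  mu <- colMeans(X)
  sdev <- if (scale) pmax(apply(X, 2, stats::sd), 1e-12) else rep(1, ncol(X))
  Xc <- sweep(sweep(X, 2, mu), 2, sdev, `/`)
  ym <- mean(y)
  yc <- y - ym

  cvFolds <- min(cvFolds, n)
  fold <- withSeed(seed, sample(rep(seq_len(cvFolds), length.out = n)))
  sqErr <- matrix(NA_real_, n, maxLV)
  for (f in seq_len(cvFolds)) {
    tr <- fold != f
    fit <- .simpls(scale(Xc[tr, , drop = FALSE], scale = FALSE), yc[tr] - mean(yc[tr]),
                   maxLV)
    trMu <- colMeans(Xc[tr, , drop = FALSE])
    Xte <- sweep(Xc[!tr, , drop = FALSE], 2, trMu)
    for (a in seq_len(fit$nComp)) {
      beta <- fit$weights[, seq_len(a), drop = FALSE] %*% fit$yLoadings[seq_len(a)]
      pred <- drop(Xte %*% beta) + mean(yc[tr]) + ym
      sqErr[!tr, a] <- (y[!tr] - pred)^2
    }
    # components unreachable in this fold inherit the last reachable one
    if (fit$nComp < maxLV && fit$nComp > 0)
      for (a in seq(fit$nComp + 1, maxLV))
        sqErr[!tr, a] <- sqErr[!tr, fit$nComp]
  }
  rmsecv <- sqrt(colMeans(sqErr))
  aStar <- which.min(rmsecv)
  foldRMSE <- vapply(seq_len(cvFolds), function(f)
    sqrt(mean(sqErr[fold == f, aStar])), numeric(1))
  se <- stats::sd(foldRMSE) / sqrt(cvFolds)
  nLV <- which(rmsecv <= rmsecv[aStar] + se)[1]

  fit <- .simpls(Xc, yc, maxLV)
  nLV <- min(nLV, fit$nComp)
  beta <- drop(fit$weights[, seq_len(nLV), drop = FALSE] %*%
                 fit$yLoadings[seq_len(nLV)])
  new("PLSRModel",
      coefficients = beta,
      intercept = ym - sum(beta * mu / sdev),
      nLV = as.integer(nLV),
      weights = fit$weights,
      loadings = fit$loadings,
      yLoadings = fit$yLoadings,
      xMeans = mu, xScales = sdev, yMean = ym,
      rmsecv = rmsecv,
      featureWavelengths = if (is.null(wavelengths)) numeric(0) else wavelengths,
      parameter = parameter,
      provenance = provenance)
}

#' @describeIn fitPLSR predict from a fitted PLSR model; affine in the
#'   predictors.
#' @param object a `PLSRModel`.
#' @param newdata samples-by-features matrix matching the training features.
#' @param ... ignored.
#' @export
setMethod("predict", "PLSRModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) return(numeric(0))
  if (ncol(newdata) != length(object@xMeans))
    stop("newdata has ", ncol(newdata), " features; model expects ",
         length(object@xMeans))
  drop(sweep(newdata, 2, object@xScales, `/`) %*% object@coefficients) +
    object@intercept
})

#' Fit an RBF support-vector regression with Monte-Carlo CV grid search
#'
#' Grid search over the penalty `c = 10^u` and kernel width `g = 10^v` with
#' `u, v` spanning \[-1, 1\]: for every grid point, repeated random
#' calibration/hold-out splits are evaluated and the pair minimising the
#' mean hold-out RMSE wins (ties to smaller `c`, then smaller `g`).
#' Predictors and response are standardised internally; epsilon defaults to
#' 0.01 x sd(y).
#'
#' @param X numeric samples-by-features matrix (calibration set).
#' @param y response vector (>= 10 samples).
#' @param cExponents,gExponents log10 grids for `c` and `g` (11 points over
#'   \[-1, 1\] by default).
#' @param nMcSplits number of Monte-Carlo splits (default 50).
#' @param holdout hold-out fraction per split (default 0.2).
#' @param epsilon insensitive-tube width on the original response scale
#'   (default `0.01 * sd(y)`).
#' @param seed seed for the split stream.
#' @param wavelengths,parameter,provenance stored metadata, as in [fitPLSR()].
#' @return An [SVRModel].
#' @export
fitSVR <- function(X, y, cExponents = seq(-1, 1, length.out = 11),
                   gExponents = seq(-1, 1, length.out = 11),
                   nMcSplits = 50, holdout = 0.2, epsilon = NULL, seed = 1,
                   wavelengths = NULL, parameter = "y", provenance = list()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("y must have one value per row of X")
  if (n < 10) stop("SVR tuning requires at least 10 calibration samples")
  ysd <- stats::sd(y)
  if (ysd < .Machine$double.eps * 100) stop("degenerate response: constant y")
  if (length(cExponents) == 0 || length(gExponents) == 0) stop("empty grid")
  if (is.null(epsilon)) epsilon <- 0.01 * ysd

  mu <- colMeans(X)
  sdev <- pmax(apply(X, 2, stats::sd), 1e-12)
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, `/`)
  ym <- mean(y)
  ys <- (y - ym) / ysd
  epsS <- epsilon / ysd

  costs <- 10^cExponents
  gammas <- 10^gExponents
  nHold <- max(1, floor(holdout * n))
  splits <- withSeed(seed, lapply(seq_len(nMcSplits), function(i)
    sample(n, nHold)))

  err <- matrix(0, length(costs), length(gammas),
                dimnames = list(sprintf("c=%g", costs), sprintf("g=%g", gammas)))
  for (sp in splits) {
    tr <- setdiff(seq_len(n), sp)
    for (ci in seq_along(costs)) for (gi in seq_along(gammas)) {
      fit <- e1071::svm(Xs[tr, , drop = FALSE], ys[tr], type = "eps-regression",
                        kernel = "radial", cost = costs[ci], gamma = gammas[gi],
                        epsilon = epsS, scale = FALSE)
      pred <- predict(fit, Xs[sp, , drop = FALSE])
      err[ci, gi] <- err[ci, gi] + sqrt(mean((ys[sp] - pred)^2))
    }
  }
  err <- err / length(splits) * ysd  # mean hold-out RMSE, original scale

  best <- c(1, 1)
  for (ci in seq_along(costs)) for (gi in seq_along(gammas))
    if (err[ci, gi] < err[best[1], best[2]]) best <- c(ci, gi)
  # ties: smaller c, then smaller g (the c-major scan keeps the first
  # strict minimum; equal values never replace it)
  bestCost <- costs[best[1]]
  bestGamma <- gammas[best[2]]

  fit <- e1071::svm(Xs, ys, type = "eps-regression", kernel = "radial",
                    cost = bestCost, gamma = bestGamma, epsilon = epsS,
                    scale = FALSE)
  new("SVRModel",
      fit = fit,
      cost = bestCost, gamma = bestGamma, epsilon = epsilon,
      gridRMSE = err,
      cvRMSE = err[best[1], best[2]],
      xMeans = mu, xScales = sdev, yMean = ym, yScale = ysd,
      featureWavelengths = if (is.null(wavelengths)) numeric(0) else wavelengths,
      parameter = parameter,
      provenance = provenance)
}

#' @describeIn fitSVR predict from a fitted SVR model. Works both with the
#'   embedded `e1071` fit and with a model rebuilt from its JSON
#'   serialisation (kernel expansion over stored support vectors).
#' @param object an `SVRModel`.
#' @param newdata samples-by-features matrix matching the training features.
#' @param ... ignored.
#' @export
setMethod("predict", "SVRModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) return(numeric(0))
  if (ncol(newdata) != length(object@xMeans))
    stop("newdata has ", ncol(newdata), " features; model expects ",
         length(object@xMeans))
  Xs <- sweep(sweep(newdata, 2, object@xMeans), 2, object@xScales, `/`)
  predS <- if (inherits(object@fit, "svm")) {
    as.numeric(predict(object@fit, Xs))
  } else {
    sv <- object@fit$SV
    d2 <- outer(rowSums(Xs^2), rowSums(sv^2), `+`) - 2 * Xs %*% t(sv)
    drop(exp(-object@gamma * d2) %*% object@fit$coefs) - object@fit$rho
  }
  predS * object@yScale + object@yMean
})
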