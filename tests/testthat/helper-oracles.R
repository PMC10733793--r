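# Independent oracles and small fixture builders shared across the suite.
# Each oracle re-derives the quantity from its definition by a route
# disjoint from the package implementation.

# Eq.-level CWT oracle: explicit trapezoidal quadrature of the wavelet
# integral with a directly sampled, untruncated Gaus1 on the 1-nm grid.
cwtQuadratureOracle <- function(f, scaleIndex) {
  a <- 2^scaleIndex
  p <- length(f)
  vapply(seq_len(p), function(b) {
    u <- (seq_len(p) - b) / a
    psi <- -u * exp(-u^2 / 2) / sqrt(a)
    w <- rep(1, p)
    w[c(1, p)] <- 0.5
    sum(f * psi * w)
  }, numeric(1))
}

# SPA chain oracle: explicit Gram-Schmidt with argmax of residual norms,
# recomputing the projection onto the selected span from scratch (QR via
# lm.fit) at every step.
spaChainOracle <- function(X, start, k) {
  X <- scale(X, center = TRUE, scale = FALSE)
  sel <- integer(0)
  current <- as.integer(start)
  for (s in seq_len(k)) {
    sel <- c(sel, current)
    if (s == k) break
    resid <- apply(X, 2, function(col) {
      fit <- stats::lm.fit(X[, sel, drop = FALSE], col)
      sqrt(sum(fit$residuals^2))
    })
    resid[sel] <- -Inf
    current <- which.max(resid)
  }
  sel
}

# OLS normal-equations oracle on centred data
olsOracle <- function(X, y) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  beta <- solve(crossprod(Xc), crossprod(Xc, yc))
  list(coefficients = drop(beta),
       intercept = mean(y) - sum(colMeans(X) * beta))
}

# small smooth random spectrum on the canonical grid
randomSmoothSpectrum <- function(seed) {
  withr::with_seed(seed, {
    wl <- canonicalGrid()
    0.35 + 0.15 * sin(wl / runif(1, 120, 260)) +
      0.08 * exp(-(wl - runif(1, 600, 2200))^2 / (2 * runif(1, 40, 120)^2))
  })
}

# small deterministic regression fixture
smallRegression <- function(seed, n = 40, p = 6, noise = 0.05) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    beta <- rnorm(p)
    y <- drop(X %*% beta) + rnorm(n, sd = noise)
    list(X = X, y = y, beta = beta)
  })
}
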