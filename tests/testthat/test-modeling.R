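test_that("PLSR fits a noise-free linear response exactly at full rank", {
  fx <- smallRegression(21, n = 30, p = 5, noise = 0)
  fit <- fitPLSR(fx$X, fx$y, maxLV = 5, cvFolds = 5)
  expect_lt(max(abs(predict(fit, fx$X) - fx$y)), 1e-10)
})

test_that("univariate PLSR with one LV is the least-squares line", {
  withr::with_seed(22, {
    x <- matrix(rnorm(50), 50, 1)
    y <- 2 + 3 * x[, 1] + rnorm(50, sd = 0.4)
  })
  fit <- fitPLSR(x, y, maxLV = 1, cvFolds = 5)
  ls <- stats::lm(y ~ x)
  expect_equal(predict(fit, x), unname(stats::fitted(ls)), tolerance = 1e-10)
})

test_that("PLSR at full rank reproduces OLS normal equations", {
  for (seed in c(23, 24, 25)) {
    fx <- smallRegression(seed, n = 35, p = 6, noise = 0.2)
    fit <- fitPLSR(fx$X, fx$y, maxLV = 6, cvFolds = 5)
    # force the full-rank model regardless of the CV choice
    beta <- drop(fit@weights %*% fit@yLoadings)
    o <- olsOracle(fx$X, fx$y)
    expect_lt(max(abs(beta - o$coefficients)), 1e-8)
  }
})

test_that("LV selection is monotone and honours the one-SE rule", {
  fx <- smallRegression(26, n = 60, p = 10, noise = 0.5)
  fit <- fitPLSR(fx$X, fx$y, maxLV = 8, cvFolds = 6)
  rmsecv <- fit@rmsecv
  aStar <- which.min(rmsecv)
  expect_lte(fit@nLV, aStar)
  # never choose more LVs than a model whose RMSECV is not lower
  expect_true(all(rmsecv[seq_len(fit@nLV - 1)] > rmsecv[fit@nLV] |
                    seq_len(fit@nLV - 1) >= fit@nLV))
})

test_that("PLSR prediction is affine and validates dimensions", {
  fx <- smallRegression(27, n = 30, p = 4, noise = 0.1)
  fit <- fitPLSR(fx$X, fx$y, maxLV = 3, cvFolds = 5)
  X1 <- fx$X[1:5, ]
  X2 <- fx$X[6:10, ]
  a <- 0.3
  expect_equal(predict(fit, a * X1 + (1 - a) * X2),
               a * predict(fit, X1) + (1 - a) * predict(fit, X2),
               tolerance = 1e-10)
  expect_length(predict(fit, fx$X[0, , drop = FALSE]), 0)
  expect_error(predict(fit, fx$X[, 1:3]), "features")
  expect_error(fitPLSR(fx$X, rep(1, 30)), "constant")
  expect_error(fitPLSR(fx$X, fx$y, maxLV = 30), "below the number")
})

test_that("SVR grid winner matches an exhaustive re-evaluation", {
  fx <- smallRegression(31, n = 40, p = 3, noise = 0.3)
  ce <- seq(-1, 1, length.out = 5)
  ge <- seq(-1, 1, length.out = 5)
  fit <- fitSVR(fx$X, fx$y, cExponents = ce, gExponents = ge,
                nMcSplits = 8, seed = 7)
  # independent re-evaluation: same split stream, plain loops
  n <- nrow(fx$X)
  mu <- colMeans(fx$X); sdev <- pmax(apply(fx$X, 2, sd), 1e-12)
  Xs <- sweep(sweep(fx$X, 2, mu), 2, sdev, `/`)
  ys <- (fx$y - mean(fx$y)) / sd(fx$y)
  splits <- withr::with_seed(7, lapply(1:8, function(i) sample(n, floor(0.2 * n))))
  err <- matrix(0, 5, 5)
  for (sp in splits) for (ci in 1:5) for (gi in 1:5) {
    m <- e1071::svm(Xs[-sp, ], ys[-sp], type = "eps-regression",
                    kernel = "radial", cost = 10^ce[ci], gamma = 10^ge[gi],
                    epsilon = 0.01, scale = FALSE)
    err[ci, gi] <- err[ci, gi] + sqrt(mean((ys[sp] - predict(m, Xs[sp, ]))^2))
  }
  idx <- which(err == min(err), arr.ind = TRUE)[1, ]
  expect_equal(fit@cost, 10^ce[idx["row"]])
  expect_equal(fit@gamma, 10^ge[idx["col"]])
})

test_that("SVR tuning is reproducible bit-for-bit under a fixed seed", {
  fx <- smallRegression(32, n = 40, p = 4, noise = 0.3)
  f1 <- fitSVR(fx$X, fx$y, cExponents = seq(-1, 1, length.out = 3),
               gExponents = seq(-1, 1, length.out = 3), nMcSplits = 5, seed = 3)
  f2 <- fitSVR(fx$X, fx$y, cExponents = seq(-1, 1, length.out = 3),
               gExponents = seq(-1, 1, length.out = 3), nMcSplits = 5, seed = 3)
  expect_identical(f1@gridRMSE, f2@gridRMSE)
  expect_identical(predict(f1, fx$X), predict(f2, fx$X))
})

test_that("SVR rejects degenerate inputs", {
  fx <- smallRegression(33, n = 12, p = 3, noise = 0.1)
  expect_error(fitSVR(fx$X[1:5, ], fx$y[1:5]), "at least 10")
  expect_error(fitSVR(fx$X, rep(2, 12)), "degenerate")
  expect_error(fitSVR(fx$X, fx$y, cExponents = numeric(0)), "empty grid")
})

test_that("default SVR grid spans c, g in [0.1, 10] on 11 points", {
  fx <- smallRegression(34, n = 30, p = 3, noise = 0.3)
  fit <- fitSVR(fx$X, fx$y, nMcSplits = 2, seed = 1)
  expect_equal(dim(fit@gridRMSE), c(11L, 11L))
  expect_true(fit@cost >= 0.1 && fit@cost <= 10)
  expect_true(fit@gamma >= 0.1 && fit@gamma <= 10)
  expect_equal(fit@epsilon, 0.01 * sd(fx$y))
})

test_that("models serialise to JSON and predict identically after reload", {
  fx <- smallRegression(35, n = 40, p = 5, noise = 0.2)
  tmp <- withr::local_tempdir()
  pls <- fitPLSR(fx$X, fx$y, maxLV = 4, cvFolds = 5,
                 wavelengths = 600:604, parameter = "Pn",
                 provenance = list(preprocessing = "CWT-4", scaleIndex = 4))
  f <- file.path(tmp, "pls.json")
  writeModelJSON(pls, f)
  pls2 <- readModelJSON(f)
  expect_equal(predict(pls2, fx$X), predict(pls, fx$X), tolerance = 1e-12)
  expect_equal(pls2@provenance$preprocessing, "CWT-4")

  svr <- fitSVR(fx$X, fx$y, cExponents = c(-1, 0, 1), gExponents = c(-1, 0, 1),
                nMcSplits = 4, seed = 2, wavelengths = 600:604, parameter = "Pn")
  g <- file.path(tmp, "svr.json")
  writeModelJSON(svr, g)
  svr2 <- readModelJSON(g)
  # reloaded model predicts via the explicit kernel expansion
  expect_equal(predict(svr2, fx$X), predict(svr, fx$X), tolerance = 1e-8)
})
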