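test_that("scenario validation rejects bad inputs", {
  expect_error(salinityScenario("S5", 30, 10), "unknown group")
  expect_error(salinityScenario("S0", 25, 10), "day must be")
  expect_error(salinityScenario("S0", 30, 0), "positive")
  sc <- salinityScenario("S2", day = 20, nSamples = 7)
  expect_equal(sc$naclGPerKg, 5.5)
})

test_that("generated parameters hit configured group means and round-trip", {
  p <- generateCFPGEParams(salinityScenario("S0", 30, 500), seed = 1)
  expect_equal(mean(p$Ci), 194.06, tolerance = 1e-10)
  expect_equal(mean(p$NPQ), 2.00, tolerance = 1e-10)
  # all six fluorescence parameters re-derive exactly from the raw yields
  rt <- deriveFluorescence(p[, c("F0", "Fm", "Fs", "F0p", "Fmp", "PAR")])
  for (v in c("PhiPSII", "FvFm", "FvF0", "qP", "NPQ", "ETR"))
    expect_lt(max(abs(rt[[v]] - p[[v]]) / pmax(abs(p[[v]]), 1e-12)), 1e-9)
  # raw-yield physical ordering
  expect_true(all(p$F0 > 0 & p$F0 < p$Fm))
  expect_true(all(p$F0p > 0 & p$F0p < p$Fmp & p$Fmp <= p$Fm))
  expect_true(all(p$F0p <= p$Fs & p$Fs <= p$Fmp))
})

test_that("zero noise collapses every sample onto the group mean", {
  p <- generateCFPGEParams(salinityScenario("S1", 30, 8), noiseScale = 0, seed = 5)
  for (v in c("Pn", "Tr", "gs", "Ci", "NPQ"))
    expect_equal(diff(range(p[[v]])), 0)
  expect_equal(p$Ci[1], 240.39)
})

test_that("group means follow the salinity dose-response sign pattern", {
  for (seed in c(2, 17)) {
    ss <- generateDataset(defaultSimConfig(nPerGroup = 30, seed = seed))
    tab <- cfpgeTable(ss)
    gm <- aggregate(tab[, cfpgeParameterNames()], list(group = tab$group), mean)
    gm <- gm[order(gm$group), ]
    for (v in c("Pn", "Tr", "gs", "PhiPSII", "FvFm", "FvF0", "qP", "ETR"))
      expect_true(all(diff(gm[[v]]) < 0), label = paste(v, "decreasing"))
    for (v in c("Ci", "NPQ"))
      expect_true(all(diff(gm[[v]]) > 0), label = paste(v, "increasing"))
  }
})

test_that("baseline carries the canonical green-leaf shape", {
  wl <- canonicalGrid()
  r <- baselineReflectance(wl)
  expect_true(all(r > 0 & r < 1))
  g <- r[wl == 553]
  expect_gt(g, max(r[wl %in% c(450, 680)]))      # green peak
  expect_lt(r[wl == 677], r[wl == 630])          # red absorption dip
  expect_true(all(diff(r[wl >= 700 & wl <= 760]) > 0))  # monotone red edge
  expect_gt(mean(r[wl >= 760 & wl <= 1100]), g)  # NIR plateau above visible
  expect_lt(r[wl == 1450], r[wl == 1300])        # water troughs
  expect_lt(r[wl == 1940], r[wl == 1800])
})

test_that("noise-free spectrum with zero depth coefficients equals the baseline", {
  feats <- defaultBandFeatures()
  feats$depthCoefficient <- 0
  rec <- generateCFPGEParams(salinityScenario("S0", 30, 1), seed = 1)
  sp <- generateSpectrum(rec, feats, noiseSd = 0,
                         scatterSd = c(multiplicative = 0, offset = 0, tilt = 0),
                         wiggleSd = 0, depthJitterSd = 0, seed = 1)
  expect_equal(sp, baselineReflectance(), tolerance = 1e-12)
})

test_that("a planted feature only perturbs its own support", {
  rec1 <- generateCFPGEParams(salinityScenario("S0", 30, 1), noiseScale = 0, seed = 1)
  rec2 <- rec1
  rec2$NPQ <- rec2$NPQ + 1
  feats <- bandFeature(578, 8, 0.02, "NPQ")
  noiseless <- function(r) generateSpectrum(
    r, feats, noiseSd = 0,
    scatterSd = c(multiplicative = 0, offset = 0, tilt = 0),
    wiggleSd = 0, depthJitterSd = 0, seed = 3)
  d <- abs(noiseless(rec1) - noiseless(rec2))
  wl <- canonicalGrid()
  expect_gt(d[wl == 578], 0.01)
  expect_true(all(d[abs(wl - 578) > 60] < 1e-12))
})

test_that("salinity raises NIR and lowers the green peak at the record level", {
  s0 <- generateCFPGEParams(salinityScenario("S0", 30, 1), noiseScale = 0, seed = 1)
  s3 <- generateCFPGEParams(salinityScenario("S3", 30, 1), noiseScale = 0, seed = 1)
  noiseless <- function(r) generateSpectrum(
    r, noiseSd = 0, scatterSd = c(multiplicative = 0, offset = 0, tilt = 0),
    wiggleSd = 0, depthJitterSd = 0, seed = 2)
  wl <- canonicalGrid()
  sp0 <- noiseless(s0); sp3 <- noiseless(s3)
  expect_lt(sp3[wl == 553], sp0[wl == 553])
  expect_gt(mean(sp3[wl >= 760 & wl <= 1100]), mean(sp0[wl >= 760 & wl <= 1100]))
})

test_that("feature centres outside the grid are rejected", {
  expect_error(bandFeature(300, 8, 0.1, "Pn"), "outside")
  expect_error(bandFeature(2600, 8, 0.1, "Pn"), "outside")
  expect_error(bandFeature(600, -1, 0.1, "Pn"), "width")
  bad <- defaultSimConfig(nPerGroup = 2)
  bad$features <- data.frame(center = 700, width = 8,
                             depthCoefficient = 0.1, driver = "NoSuch")
  expect_error(generateDataset(bad), "unknown driving parameter")
})

test_that("datasets are deterministic, complete and in [0,1]", {
  cfg <- defaultSimConfig(nPerGroup = 5, seed = 42)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(spectraMatrix(a), spectraMatrix(b))
  expect_identical(cfpgeTable(a), cfpgeTable(b))
  expect_equal(dim(spectraMatrix(a)), c(20L, 2151L))
  expect_true(all(spectraMatrix(a) >= 0 & spectraMatrix(a) <= 1))
  expect_error(generateDataset(list(scenarios = list())), "at least one")

  one <- defaultSimConfig(nPerGroup = 1, seed = 3)
  one$scenarios <- one$scenarios[1]
  d1 <- generateDataset(one)
  expect_equal(dim(spectraMatrix(d1)), c(1L, 2151L))
})

test_that("per-scenario RNG streams are independent of the scenario list", {
  base <- defaultSimConfig(nPerGroup = 4, seed = 9)
  sub <- base
  sub$scenarios <- base$scenarios[c(1, 3)]
  full <- generateDataset(base)
  part <- generateDataset(sub)
  keep <- cfpgeTable(full)$group %in% c("S0", "S2")
  expect_equal(unname(spectraMatrix(full)[keep, ]),
               unname(spectraMatrix(part)))
})
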