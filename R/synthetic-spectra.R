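#' Analytic baseline leaf reflectance
#'
#' A piecewise-smooth sum of sigmoids and Gaussians with the canonical
#' features of a green-leaf spectrum: low visible reflectance with a green
#' peak near 553 nm, strong chlorophyll absorption near 675--690 nm, a
#' monotone red edge over 700--760 nm, a near-infrared plateau, and water
#' absorption troughs near 1450 and 1940 nm. Not a radiative-transfer model;
#' it only has to carry planted absorption features.
#'
#' @param wl wavelengths (nm); defaults to the canonical grid.
#' @return Numeric reflectance vector in (0, 1).
#' @export
#' @examples
#' r <- baselineReflectance()
#' r[canonicalGrid() == 553] > r[canonicalGrid() == 677]
baselineReflectance <- function(wl = canonicalGrid()) {
  sig <- function(x) 1 / (1 + exp(-x))
  0.17 +
    0.13 * exp(-(wl - 553)^2 / (2 * 35^2)) -   # green peak
    0.07 * exp(-(wl - 420)^2 / (2 * 35^2)) -   # blue absorption
    0.06 * exp(-(wl - 677)^2 / (2 * 15^2)) +   # chlorophyll-a red absorption
    0.38 * sig((wl - 715) / 12) -              # red edge -> NIR plateau
    0.22 * exp(-(wl - 1450)^2 / (2 * 40^2)) -  # water absorption
    0.28 * exp(-(wl - 1940)^2 / (2 * 55^2)) -  # water absorption
    0.12 * sig((wl - 1800) / 250) -            # SWIR decline
    0.10 * sig((wl - 2200) / 150)
}

#' Define a planted absorption feature
#'
#' A Gaussian-shaped absorption subtracted from the baseline with depth
#' `depthCoefficient * record[[driver]]`, i.e. the feature deepens linearly
#' in its driving CFPGE parameter. Negative coefficients add reflectance
#' (used for the NIR brightening under salinity).
#'
#' @param center centre wavelength (nm), inside 350--2500.
#' @param width Gaussian standard deviation (nm), > 0.
#' @param depthCoefficient reflectance units per unit of the driver.
#' @param driver name of a CFPGE parameter column.
#' @return One-row `data.frame`.
#' @export
bandFeature <- function(center, width, depthCoefficient, driver) {
  if (center < 350 || center > 2500)
    stop("feature center ", center, " nm outside the 350-2500 nm grid")
  if (width <= 0) stop("feature width must be positive")
  data.frame(center = center, width = width,
             depthCoefficient = depthCoefficient, driver = driver)
}

#' Default planted band features
#'
#' Encodes the band-to-parameter assignments the pipeline is exercised
#' against. FvFm drives the red-region set (675, 680, 688, 749, 782 nm) and
#' the non-red set (578, 976, 1088, 1476, 2250 nm); the other parameters get
#' absorption features at their reported sites (qP at 460/1019, Tr at
#' 482/1453, PhiPSII at 1600/2250, NPQ/Ci/ETR in 1450--1650, Pn and gs near
#' 2100, FvF0 in 900--1000). Two broad NPQ-driven structures darken the
#' green peak and brighten the 760--1100 nm plateau as salinity rises.
#'
#' Depth coefficients are calibrated so that, at the default measurement
#' noise, red-region information alone supports only moderate FvFm recovery
#' while the fused regions support strong recovery (the contrast the
#' pipeline is designed to expose).
#'
#' @return `data.frame` of [bandFeature()] rows.
#' @export
defaultBandFeatures <- function() {
  rbind(
    # FvFm: red-region features (weak, mutually overlapping)
    bandFeature(675, 8, 0.045, "FvFm"),
    bandFeature(680, 8, 0.045, "FvFm"),
    bandFeature(688, 8, 0.045, "FvFm"),
    bandFeature(749, 8, 0.045, "FvFm"),
    bandFeature(782, 8, 0.045, "FvFm"),
    # FvFm: blue-green + NIR features (strong, well separated)
    bandFeature(578, 8, 0.25, "FvFm"),
    bandFeature(976, 8, 0.25, "FvFm"),
    bandFeature(1088, 8, 0.25, "FvFm"),
    bandFeature(1476, 8, 0.25, "FvFm"),
    bandFeature(2250, 8, 0.25, "FvFm"),
    # other parameters
    bandFeature(460, 8, 0.08, "qP"),
    bandFeature(1019, 8, 0.10, "qP"),
    bandFeature(482, 8, 0.012, "Tr"),
    bandFeature(1453, 8, 0.012, "Tr"),
    bandFeature(1600, 8, 0.15, "PhiPSII"),
    bandFeature(2250, 8, 0.10, "PhiPSII"),
    bandFeature(1500, 8, 0.02, "NPQ"),
    bandFeature(1550, 8, 4e-4, "Ci"),
    bandFeature(1650, 8, 3e-4, "ETR"),
    bandFeature(2100, 8, 0.004, "Pn"),
    bandFeature(2132, 8, 0.07, "gs"),
    bandFeature(943, 8, 0.012, "FvF0"),
    # broad salinity-trend structures (driver NPQ increases with salinity)
    bandFeature(553, 20, 0.03, "NPQ"),   # visible darkening
    bandFeature(850, 70, -0.02, "NPQ")   # NIR brightening
  )
}

# depth matrix (n x bands) for a set of features given the parameter table;
# `jitter` (n x n_features) adds per-sample, per-feature depth deviations
.featureDepths <- function(records, features, wl, jitter = NULL) {
  depth <- matrix(0, nrow(records), length(wl))
  for (k in seq_len(nrow(features))) {
    f <- features[k, ]
    if (f$center < 350 || f$center > 2500)
      stop("feature center ", f$center, " nm outside the 350-2500 nm grid")
    driver <- records[[f$driver]]
    if (is.null(driver))
      stop("unknown driving parameter: ", f$driver)
    shape <- exp(-(wl - f$center)^2 / (2 * f$width^2))
    d <- f$depthCoefficient * driver
    if (!is.null(jitter)) d <- d + jitter[, k]
    depth <- depth + d %o% shape
  }
  depth
}

#' Generate one leaf spectrum from a CFPGE record
#'
#' Subtracts each feature's Gaussian absorption (depth = coefficient x
#' driving parameter) from the analytic baseline, applies per-sample scatter
#' distortions (multiplicative amplitude, additive offset, linear tilt) and
#' i.i.d. Gaussian band noise, and clips to [0, 1].
#'
#' @param record one-row `data.frame` of CFPGE parameters (any driver named
#'   by `features` must be present).
#' @param features `data.frame` of [bandFeature()] rows.
#' @param noiseSd standard deviation of the additive band noise
#'   (reflectance units; default 0.002).
#' @param scatterSd named numeric: `multiplicative` (sd of the amplitude
#'   factor), `offset` (sd of the additive offset) and `tilt` (sd of the
#'   linear slope per nm). Set to zeros for a noise-free spectrum.
#' @param wiggleSd coefficient sd of the smooth random-baseline nuisance
#'   (Gaussian bumps every 100 nm, width sd 80 nm), emulating the
#'   high-dimensional scatter/baseline variation of field spectra that
#'   motivates wavelet preprocessing; 0 disables it.
#' @param depthJitterSd sd of independent per-feature depth deviations
#'   (reflectance units), emulating constituent heterogeneity: real
#'   absorption depths are never exact linear functions of a single
#'   physiological parameter; 0 disables it.
#' @param seed RNG seed.
#' @return Numeric reflectance vector on the canonical 2151-band grid.
#' @export
generateSpectrum <- function(record, features = defaultBandFeatures(),
                             noiseSd = 0.002,
                             scatterSd = c(multiplicative = 0.03,
                                           offset = 0.015, tilt = 8e-6),
                             wiggleSd = 0.002, depthJitterSd = 0.002,
                             seed = 1) {
  wl <- canonicalGrid()
  record <- as.data.frame(record)
  B <- .wiggleBasis(wl)
  withSeed(seed, {
    jit <- if (depthJitterSd > 0)
      matrix(rnorm(nrow(features), sd = depthJitterSd), 1) else NULL
    depth <- .featureDepths(record, features, wl, jit)
    clean <- baselineReflectance(wl) - drop(depth)
    m <- 1 + scatterSd[["multiplicative"]] * rnorm(1)
    o <- scatterSd[["offset"]] * rnorm(1)
    tl <- scatterSd[["tilt"]] * rnorm(1)
    wig <- if (wiggleSd > 0) drop((wiggleSd * rnorm(nrow(B))) %*% B) else 0
    eps <- if (noiseSd > 0) rnorm(length(wl), sd = noiseSd) else 0
    pmin(pmax(m * clean + o + tl * (wl - mean(wl)) + wig + eps, 0), 1)
  })
}

# smooth nuisance basis: Gaussian bumps every 100 nm, width sd 80 nm;
# rank ~22, concentrated at coarse wavelet scales
.wiggleBasis <- function(wl) {
  centers <- seq(350, 2500, by = 100)
  t(vapply(centers, function(cc) exp(-(wl - cc)^2 / (2 * 80^2)),
           numeric(length(wl))))
}

#' Default simulation configuration
#'
#' The standard study conditions: four salinity groups (S0--S3) of
#' `nPerGroup` leaves each at one sampling day (240 spectra per date at the
#' default 60), the default planted band features, band noise sd 0.002 and
#' the default scatter distortions.
#'
#' @param day sampling day (default 30, the peak-response date).
#' @param nPerGroup leaves per group (default 60).
#' @param seed base seed; per-scenario streams are derived from it.
#' @param noiseSd,scatterSd,wiggleSd,depthJitterSd,features,noiseScale,par
#'   see [generateSpectrum()] and [generateCFPGEParams()].
#' @return A list understood by [generateDataset()].
#' @export
defaultSimConfig <- function(day = 30, nPerGroup = 60, seed = 1,
                             noiseSd = 0.002,
                             scatterSd = c(multiplicative = 0.03,
                                           offset = 0.015, tilt = 8e-6),
                             wiggleSd = 0.002, depthJitterSd = 0.002,
                             features = defaultBandFeatures(),
                             noiseScale = 1, par = 1200) {
  list(
    scenarios = lapply(c("S0", "S1", "S2", "S3"), salinityScenario,
                       day = day, nSamples = nPerGroup),
    features = features,
    noiseSd = noiseSd,
    scatterSd = scatterSd,
    wiggleSd = wiggleSd,
    depthJitterSd = depthJitterSd,
    noiseScale = noiseScale,
    par = par,
    seed = seed
  )
}

# content-keyed per-scenario seed: adding a scenario never perturbs others
.scenarioSeed <- function(baseSeed, scenario) {
  g <- match(scenario$group, c("S0", "S1", "S2", "S3")) - 1L
  as.integer((as.numeric(baseSeed) + 1009 * g + 131 * scenario$day) %% 2147483629)
}

#' Generate a full synthetic dataset
#'
#' Runs [generateCFPGEParams()] and the spectral forward model for every
#' scenario in the configuration and assembles a [SpectraSet]. Each scenario
#' uses a private RNG stream keyed by (base seed, group, day), so datasets
#' are bit-identical under a fixed seed and adding a scenario does not
#' perturb the others.
#'
#' @param config list as produced by [defaultSimConfig()].
#' @return A [SpectraSet] with the CFPGE table (and raw fluorescence yields)
#'   in `colData`.
#' @export
#' @examples
#' ss <- generateDataset(defaultSimConfig(nPerGroup = 3, seed = 7))
#' dim(ss)
generateDataset <- function(config) {
  if (is.null(config$scenarios) || length(config$scenarios) == 0)
    stop("config must list at least one scenario")
  wl <- canonicalGrid()
  parts <- lapply(config$scenarios, function(sc) {
    sseed <- .scenarioSeed(config$seed, sc)
    rec <- generateCFPGEParams(sc, noiseScale = config$noiseScale,
                               par = config$par, seed = sseed)
    n <- nrow(rec)
    wiggleSd <- if (is.null(config$wiggleSd)) 0 else config$wiggleSd
    jitterSd <- if (is.null(config$depthJitterSd)) 0 else config$depthJitterSd
    B <- .wiggleBasis(wl)
    spec <- withSeed(sseed + 1L, {
      jit <- if (jitterSd > 0)
        matrix(rnorm(n * nrow(config$features), sd = jitterSd), n) else NULL
      depth <- .featureDepths(rec, config$features, wl, jit)
      clean <- sweep(-depth, 2, baselineReflectance(wl), `+`)
      m <- 1 + config$scatterSd[["multiplicative"]] * rnorm(n)
      o <- config$scatterSd[["offset"]] * rnorm(n)
      tl <- config$scatterSd[["tilt"]] * rnorm(n)
      wig <- if (wiggleSd > 0)
        matrix(rnorm(n * nrow(B), sd = wiggleSd), n) %*% B else 0
      eps <- if (config$noiseSd > 0)
        matrix(rnorm(n * length(wl), sd = config$noiseSd), n) else 0
      out <- clean * m + o + tl %o% (wl - mean(wl)) + wig + eps
      pmin(pmax(out, 0), 1)
    })
    list(rec = rec, spec = spec)
  })
  rec <- do.call(rbind, lapply(parts, `[[`, "rec"))
  spec <- do.call(rbind, lapply(parts, `[[`, "spec"))
  rec <- cbind(sample_id = sprintf("%s_d%02d_%03d", rec$group, rec$day,
                                   stats::ave(seq_len(nrow(rec)), rec$group,
                                              rec$day, FUN = seq_along)),
               rec)
  rownames(rec) <- rec$sample_id
  ss <- SpectraSet(spec, wl, sampleData = rec)
  S4Vectors::metadata(ss)$simConfig <- config[c("noiseSd", "scatterSd",
                                                "wiggleSd", "depthJitterSd",
                                                "noiseScale", "par", "seed")]
  ss
}
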