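#' @importFrom stats rnorm sd approx predict quantile
#' @importFrom withr with_seed
NULL

# Run expr with a private RNG stream, leaving the caller's RNG untouched.
withSeed <- function(seed, expr) withr::with_seed(as.integer(seed), expr)

#' Salinity treatment scenario
#'
#' Describes one treatment group x sampling-date cell of the pot experiment
#' the generator emulates: NaCl mass fractions of 0 (S0), 3.5 (S1), 5.5 (S2)
#' and 7.5 (S3) g per kg soil, sampled 10, 20, 30 or 40 days after
#' transplanting.
#'
#' @param group one of `"S0" "S1" "S2" "S3"`.
#' @param day sampling day, one of 10, 20, 30, 40.
#' @param nSamples number of leaves (>= 1).
#' @param naclGPerKg NaCl mass fraction; defaults to the value implied by
#'   `group`.
#' @return A list of class `salinityScenario`.
#' @export
#' @examples
#' salinityScenario("S1", day = 30, nSamples = 60)
salinityScenario <- function(group, day = 30, nSamples = 60,
                             naclGPerKg = NULL) {
  nacl <- c(S0 = 0, S1 = 3.5, S2 = 5.5, S3 = 7.5)
  if (!group %in% names(nacl))
    stop("unknown group label: ", group, " (expected S0..S3)")
  if (!day %in% c(10, 20, 30, 40))
    stop("day must be one of 10, 20, 30, 40")
  if (length(nSamples) != 1 || is.na(nSamples) || nSamples < 1)
    stop("nSamples must be a positive integer")
  structure(list(group = group, day = day, nSamples = as.integer(nSamples),
                 naclGPerKg = if (is.null(naclGPerKg)) nacl[[group]] else naclGPerKg),
            class = "salinityScenario")
}

# Reference group means of the primary generated parameters. Gas-exchange
# rates peak on day 40 (refDay 40); Ci and the fluorescence ratios peak on
# day 30 (refDay 30). Fv/F0 is the primary fluorescence-ratio target; Fv/Fm
# is derived from it (FvFm = FvF0/(1+FvF0)) so the published identity holds
# exactly, and ETR follows from PhiPSII and PAR.
.groupMeanTable <- function() {
  data.frame(
    parameter = c("Pn", "Tr", "gs", "Ci", "FvF0", "qP", "PhiPSII", "NPQ"),
    refDay = c(40, 40, 40, 30, 30, 30, 30, 30),
    cv = c(0.06, 0.06, 0.08, 0.06, 0.10, 0.02, 0.03, 0.10),
    S0 = c(24.86, 8.75, 1.38, 194.06, 4.63, 0.98, 0.71, 2.00),
    S1 = c(23.39, 8.40, 1.27, 240.39, 4.27, 0.96, 0.69, 2.48),
    S2 = c(22.36, 7.83, 1.22, 257.69, 4.03, 0.93, 0.67, 2.89),
    S3 = c(20.91, 7.04, 1.21, 259.63, 3.66, 0.90, 0.66, 3.36)
  )
}

# Temporal trend multipliers: parameters peaking on day 30 rise then fall;
# gas-exchange rates climb through day 40.
.dayFactor <- function(refDay, day) {
  peak30 <- c(`10` = 0.88, `20` = 0.96, `30` = 1.00, `40` = 0.94)
  peak40 <- c(`10` = 0.80, `20` = 0.90, `30` = 0.96, `40` = 1.00)
  f <- if (refDay == 30) peak30 else peak40
  f[[as.character(day)]] / f[[as.character(refDay)]]
}

#' Configured group means for one scenario
#'
#' @param scenario a [salinityScenario()].
#' @param meanTable optional replacement for the built-in group-mean table
#'   (same columns).
#' @return Named numeric vector of the eight primary parameter means.
#' @export
scenarioMeans <- function(scenario, meanTable = NULL) {
  tab <- if (is.null(meanTable)) .groupMeanTable() else meanTable
  mu <- tab[[scenario$group]] *
    vapply(tab$refDay, .dayFactor, numeric(1), day = scenario$day)
  stats::setNames(mu, tab$parameter)
}

#' Generate CFPGE parameters and raw fluorescence yields for one scenario
#'
#' Draws per-leaf values of the gas-exchange parameters and of the primary
#' fluorescence targets (Fv/F0, qP, PhiPSII, NPQ) around the configured
#' group means, back-solves the raw saturating-pulse yields (F0, Fm, Fs,
#' F0', Fm') that reproduce those targets under the standard formulas, and
#' then *derives* all six fluorescence parameters from the raw yields with
#' [deriveFluorescence()], so the stored parameters round-trip exactly.
#'
#' Within-group deviations are recentred to zero mean, so group sample means
#' equal the configured targets exactly at any sample size (conditional
#' simulation); `noiseScale = 0` makes every sample equal its group mean.
#'
#' @param scenario a [salinityScenario()].
#' @param noiseScale multiplier on the per-parameter coefficients of
#'   variation (default 1; 0 gives degenerate noise).
#' @param par photosynthetically active radiation during the light-adapted
#'   measurement (µmol m^-2 s^-1); default 1200, the saturating-pulse value.
#' @param meanTable optional group-mean table override.
#' @param seed integer seed for this scenario's private RNG stream.
#' @return `data.frame` with one row per sample: sample metadata, the ten
#'   CFPGE parameters and the six raw fluorescence columns.
#' @export
#' @examples
#' head(generateCFPGEParams(salinityScenario("S0", 30, 5), seed = 1))
generateCFPGEParams <- function(scenario, noiseScale = 1, par = 1200,
                                meanTable = NULL, seed = 1) {
  stopifnot(inherits(scenario, "salinityScenario"))
  n <- scenario$nSamples
  tab <- if (is.null(meanTable)) .groupMeanTable() else meanTable
  mu <- scenarioMeans(scenario, tab)
  cv <- stats::setNames(tab$cv, tab$parameter) * noiseScale

  draw <- function(param) {
    z <- rnorm(n)
    if (n > 1) z <- z - mean(z)
    mu[[param]] * (1 + cv[[param]] * z)
  }

  withSeed(seed, {
    vals <- lapply(names(mu), draw)
    names(vals) <- names(mu)
    # keep the fluorescence targets inside their physical domains
    vals$qP <- pmin(vals$qP, 0.995)
    vals$PhiPSII <- pmin(vals$PhiPSII, vals$qP - 0.01)
    vals$FvF0 <- pmax(vals$FvF0, 0.05)
    vals$NPQ <- pmax(vals$NPQ, 0)
    fvfm <- vals$FvF0 / (1 + vals$FvF0)

    Fm <- 1500 * (1 + 0.05 * rnorm(n))
    F0 <- Fm * (1 - fvfm)
    Fmp <- Fm / (1 + vals$NPQ)
    Fs <- Fmp * (1 - vals$PhiPSII)
    F0p <- Fmp * (1 - vals$PhiPSII / vals$qP)
    raw <- data.frame(F0 = F0, Fm = Fm, Fs = Fs, F0p = F0p, Fmp = Fmp,
                      PAR = rep(par, n))
    fluor <- deriveFluorescence(raw)
    data.frame(
      group = scenario$group,
      nacl_g_per_kg = scenario$naclGPerKg,
      day = scenario$day,
      Pn = vals$Pn, Tr = vals$Tr, gs = vals$gs, Ci = vals$Ci,
      fluor[, c("PhiPSII", "FvFm", "FvF0", "qP", "NPQ", "ETR")],
      raw
    )
  })
}
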