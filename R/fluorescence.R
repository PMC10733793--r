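#' Derive chlorophyll-fluorescence parameters from raw yields
#'
#' Computes the six fluorescence parameters from the raw saturating-pulse
#' yields measured on dark- and light-adapted leaves:
#' \deqn{Fv/Fm = (Fm - F0)/Fm, \quad Fv/F0 = (Fm - F0)/F0,}
#' \deqn{\Phi_{PSII} = (Fm' - Fs)/Fm', \quad qP = (Fm' - Fs)/(Fm' - F0'),}
#' \deqn{NPQ = (Fm - Fm')/Fm', \quad ETR = PAR \times \Phi_{PSII} \times
#'   \alpha \times f_{PSII}}
#' with leaf absorptance \eqn{\alpha = 0.84} and PSII excitation fraction
#' \eqn{f_{PSII} = 0.5} by default.
#'
#' `qP` values above 1 (possible when `Fs < F0'` in noisy data) are returned
#' as-is with a warning; clamping would hide data problems.
#'
#' @param raw `data.frame` (or list) with columns `F0`, `Fm`, `Fs`, `F0p`,
#'   `Fmp`, `PAR` — the minimum/maximum dark-adapted yields, steady-state
#'   yield, light-adapted minimum/maximum yields and photosynthetically
#'   active radiation (µmol m^-2 s^-1).
#' @param absorptance leaf absorptance entering ETR (default 0.84).
#' @param psiiFraction fraction of absorbed quanta reaching PSII (default 0.5).
#' @return `data.frame` with columns `PhiPSII`, `FvFm`, `FvF0`, `qP`, `NPQ`,
#'   `ETR` and a logical `qP_flag` marking rows with `qP > 1`.
#' @export
#' @examples
#' deriveFluorescence(data.frame(F0 = 1, Fm = 5, Fs = 1.5, F0p = 1,
#'                               Fmp = 3, PAR = 1000))
deriveFluorescence <- function(raw, absorptance = 0.84, psiiFraction = 0.5) {
  raw <- as.data.frame(raw)
  need <- c("F0", "Fm", "Fs", "F0p", "Fmp", "PAR")
  miss <- setdiff(need, colnames(raw))
  if (length(miss))
    stop("raw fluorescence table lacks column(s): ", paste(miss, collapse = ", "))
  with(raw, {
    if (any(Fm <= 0)) stop("invalid raw yields: Fm must be positive")
    if (any(F0 >= Fm)) stop("invalid raw yields: F0 must be below Fm")
    if (any(Fmp <= 0)) stop("invalid raw yields: Fm' must be positive")
    if (any(Fmp == F0p)) stop("invalid raw yields: Fm' equals F0' (qP undefined)")
    if (any(F0 <= 0)) stop("invalid raw yields: F0 must be positive")
  })
  fvfm <- (raw$Fm - raw$F0) / raw$Fm
  fvf0 <- (raw$Fm - raw$F0) / raw$F0
  phi <- (raw$Fmp - raw$Fs) / raw$Fmp
  qp <- (raw$Fmp - raw$Fs) / (raw$Fmp - raw$F0p)
  npq <- (raw$Fm - raw$Fmp) / raw$Fmp
  etr <- raw$PAR * phi * absorptance * psiiFraction
  flag <- qp > 1
  if (any(flag))
    warning(sum(flag), " sample(s) with qP > 1 (Fs below F0'); returned unclamped")
  data.frame(PhiPSII = phi, FvFm = fvfm, FvF0 = fvf0, qP = qp,
             NPQ = npq, ETR = etr, qP_flag = flag)
}

#' Percent change of a treatment mean relative to a control mean
#'
#' @param treatmentMean,controlMean numeric values (control must be nonzero).
#' @return Signed percent, `100 * (treatment - control) / control`, unrounded.
#' @seealso [formatPercentChange()] for the two-decimal half-up display form.
#' @export
#' @examples
#' percentChange(240.39, 194.06) # +23.87... %
percentChange <- function(treatmentMean, controlMean) {
  if (any(controlMean == 0)) stop("control mean must be nonzero")
  100 * (treatmentMean - controlMean) / controlMean
}

#' Display-round a percent change to two decimals, half-up
#'
#' Base R's `round()` rounds half to even; reported percent changes use
#' conventional half-up rounding at display time only.
#'
#' @param x numeric percent values.
#' @param digits decimal places (default 2).
#' @return Numeric, rounded half-up.
#' @export
formatPercentChange <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
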