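---
title: "Estimating photosynthetic parameters from leaf spectra: methods and design"
author: "fluorspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating photosynthetic parameters from leaf spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorspec)
```

## The problem

Chlorophyll fluorescence and photosynthetic gas-exchange (CFPGE) parameters
— net photosynthetic rate Pn, transpiration Tr, stomatal conductance gs,
intercellular CO2 concentration Ci, and the PSII fluorescence quantities
Fv/Fm, Fv/F0, ΦPSII, qP, NPQ and ETR — quantify how stress, here soil
salinity, degrades leaf photosynthesis. Measuring them with gas analysers
and pulse-amplitude-modulated fluorometers is slow (dark adaptation,
per-leaf clamping). Leaf reflectance spectra in 350–2500 nm can be acquired
in seconds, and the physiological state leaves fingerprints in them:
pigment absorption in the visible, the red edge, and constituent bands
(water, protein, lipid) in the near infrared.

`fluorspec` implements a calibration pipeline that estimates CFPGE
parameters from such spectra:

1. **Preprocessing** — standard normal variate (SNV) normalisation, and a
   continuous wavelet transform (CWT) with a Gaus1 (first derivative of a
   Gaussian) mother wavelet at the dyadic scales 2^1 … 2^10 bands.
2. **Wavelength selection** — the successive projections algorithm (SPA)
   under spectral-region constraints: candidates restricted to the red
   region (600–800 nm; "RSF" features) or drawn from the fused blue-green
   (350–600 nm), red and near-infrared (800–2500 nm) regions ("FSF").
3. **Calibration** — partial least squares regression (SIMPLS) and
   RBF-kernel epsilon support-vector regression, tuned by Monte-Carlo
   cross-validation over penalty `c` and kernel width `g`.
4. **Evaluation** — RMSE and R² on calibration and validation sets and the
   residual prediction deviation RPD = S_D / RMSE_CV, with the stratified
   two-thirds sample split.

Because no spectral data accompany the study design this pipeline targets,
the package ships a synthetic leaf-spectra generator as a first-class,
tested module; every claim the test suite makes about the pipeline is a
claim about its behaviour on that generator.

## Fluorescence arithmetic

From the raw saturating-pulse yields (dark-adapted F0, Fm; light-adapted
Fs, F0′, Fm′; and PAR), `deriveFluorescence()` computes

* Fv/Fm = (Fm − F0)/Fm and Fv/F0 = (Fm − F0)/F0, so the identity
  Fv/Fm = (Fv/F0)/(1 + Fv/F0) holds to machine precision by construction;
* ΦPSII = (Fm′ − Fs)/Fm′, qP = (Fm′ − Fs)/(Fm′ − F0′),
  NPQ = (Fm − Fm′)/Fm′;
* ETR = PAR × ΦPSII × 0.84 × 0.5, the 0.84 (leaf absorptance) and 0.5
  (PSII excitation fraction) being exposed as arguments.

`qP` can exceed 1 when noisy data put Fs below F0′; such values are
returned unclamped with a warning flag, since clamping would hide data
problems. ΦPSII ≤ Fv/Fm is *not* enforced — it depends on the light state.

## The synthetic data generator

### Physiological parameters

Group means for four salinity treatments (S0–S3: 0, 3.5, 5.5 and
7.5 g NaCl per kg soil) at four sampling days are stored for eight primary
quantities (Pn, Tr, gs, Ci, Fv/F0, qP, ΦPSII, NPQ); gas-exchange rates
peak on day 40 and the others on day 30, with mild multiplicative day
trends. Per-leaf values are drawn as Gaussian deviations around the group
mean with parameter-specific coefficients of variation (2 % for the
tightly-bounded qP up to 10 % for NPQ and Fv/F0); deviations are recentred
to zero within each group (conditional simulation), so group sample means
equal their configured targets exactly at any sample size and the
dose–response ordering (Pn, Tr, gs, ΦPSII, Fv/Fm, Fv/F0, qP, ETR decrease
with salinity; Ci and NPQ increase) holds for every generated dataset, not
just in expectation.

The fluorescence block works backwards from the sampled targets: Fm is
drawn around 1500 a.u., then F0 = Fm(1 − Fv/Fm), Fm′ = Fm/(1 + NPQ),
Fs = Fm′(1 − ΦPSII) and F0′ = Fm′(1 − ΦPSII/qP), with PAR fixed at the
saturating-pulse value 1200 µmol m⁻² s⁻¹. The stored fluorescence
parameters are then *derived* from these raw yields, so they round-trip
through `deriveFluorescence()` exactly. Two consequences are deliberate:
Fv/F0 is the primary target and Fv/Fm ≈ 0.82 follows from it (published
group tables often print mutually inconsistent Fv/Fm and Fv/F0 values;
a self-consistent generator can match only one), and ETR follows from
ΦPSII and PAR rather than from any printed ETR table.

### Spectra

The baseline is an analytic sum of sigmoids and Gaussians with the
canonical green-leaf shape — green peak at 553 nm, chlorophyll absorption
near 677 nm, a monotone red edge over 700–760 nm rising to a NIR plateau
near 0.55, water troughs at 1450/1940 nm and a declining SWIR tail. It is
*not* a radiative-transfer model; it only has to carry planted features
with controlled headroom.

Information enters the spectra as Gaussian absorption features whose depth
is `depthCoefficient × driving parameter` plus a small independent
per-feature *depth jitter* (sd 0.002 reflectance). Fv/Fm drives a weak,
mutually overlapping red set (675, 680, 688, 749, 782 nm) and a strong,
well-separated non-red set (578, 976, 1088, 1476, 2250 nm); the other nine
parameters drive features at their characteristic sites (e.g. qP at
460/1019 nm, water-related bands near 1450–1650 nm for NPQ/Ci/ETR, bands
near 2100 nm for Pn and gs). Two broad NPQ-driven structures lower the
green peak and brighten the 760–1100 nm plateau as salinity rises,
reproducing the visible-darkening / NIR-brightening signature of salt
stress. The depth jitter matters beyond realism: absorption depths in real
leaves are never exact linear functions of one physiological scalar, and
without it all five Fv/Fm bands are mutual linear shadows of one variable —
a selector built to minimise collinearity (SPA) then correctly refuses to
keep more than two or three of them.

Nuisance terms emulate what makes field spectroscopy hard and what makes
wavelet preprocessing pay off: per-sample multiplicative amplitude scatter
(sd 3 %), additive offset (sd 0.015), a linear tilt, a smooth random
baseline ("wiggle": Gaussian bumps every 100 nm, width 80 nm, coefficient
sd 0.002 — a high-rank, long-correlation-length distortion that a
10-latent-variable regression cannot fully span but that mid-scale
wavelets suppress), and i.i.d. band noise (sd 0.002). With only low-rank
scatter, raw-spectrum PLSR is near-optimal and no preprocessing
comparison can be meaningful; the wiggle term is what gives the CWT its
documented advantage.

All levels are configurable (`defaultSimConfig()`); setting them to zero
yields exactly the deterministic baseline-plus-features model used by the
locality and identity tests. Per-scenario RNG streams are keyed by (seed,
group, day), so adding a scenario never perturbs the others and datasets
are bit-identical under a fixed seed.

### What the generator does not emulate

Detector-stitching artefacts, directional/BRDF effects, canopy structure,
chlorophyll-fluorescence emission contributions to apparent reflectance,
and any nonlinearity between constituents and absorption depth. Passing
tests therefore demonstrate that the pipeline recovers planted structure
under realistic noise — not that field data of this design would reach the
same accuracies.

## Numerical choices

* **CWT.** Coefficients are the discrete correlation of each spectrum with
  the L2-normalised (1/√a) dilated wavelet on the 1-nm grid — the printed
  form of the wavelet normalisation is typographically ambiguous between
  1/a and 1/√a, and the choice is immaterial downstream because regression
  re-weights each scale. The kernel is truncated at ±8a, where the
  neglected Gaussian tail (~e⁻³²) is far below the 1e-6 agreement the test
  suite demands against direct quadrature; ±5a, a common choice, leaves
  ~2e-5 tails that dominate exactly where fine-scale coefficients of
  smooth spectra are small. Boundaries use symmetric (reflect) padding to
  half the support, implemented with a triangular-wave index so pads wider
  than the grid fold correctly; bands whose coefficient window touches the
  padding are flagged `edge_affected`, and at scale 2^10 that is every
  band. Convolutions run as batched FFTs at power-of-two/three lengths,
  two real spectra per complex transform.
* **SNV** divides by the sample standard deviation with denominator p − 1,
  is idempotent and affine-invariant, and refuses zero-variance spectra by
  name.
* **SPA.** The chain is greedy Gram–Schmidt pivoting (modified
  Gram–Schmidt, incremental norm updates, tolerance 1e-10 × largest column
  norm, truncation with a warning on exact collinearity), run from every
  candidate start column, with subset size chosen by validation RMSE of an
  OLS calibration model over chain prefixes; ties break to the smaller
  subset, then the lower start wavelength. Columns are centred on the
  calibration set but deliberately *not* variance-scaled: the selection
  always runs within one preprocessing, where coefficient magnitudes are
  homogeneous, and the projection chain's affinity for high-variance
  columns is precisely what steers it toward informative bands —
  autoscaling erases that signal and, on the default conditions, makes
  planted-band recovery impossible. The all-starts scan is implemented in
  C++ (RcppArmadillo).
* **PLSR** uses SIMPLS (deterministic, no iteration-order ambiguity); the
  latent-variable count minimises 10-fold RMSECV with the one-standard-error
  rule breaking near-ties toward the smaller model. At full rank the
  coefficients coincide with OLS, which the tests assert against the
  normal equations.
* **SVR** is epsilon-regression (the variant is unstated in the chemometrics
  literature this follows; epsilon-SVR is the common default) with
  epsilon = 0.01 × sd(y), grid c = 10^u, g = 10^v for u, v on 11 points
  over [−1, 1] — a "range −1 to 1" for a positive penalty parameter only
  makes sense on the log10 scale — and 50 Monte-Carlo 80/20 splits drawn
  from a seeded stream, so tuning is bit-reproducible.
* **Split.** Samples are ranked by the target, cut into three strata from
  high to low, outliers beyond 3 within-group SDs removed, and a seeded
  random two-thirds of each stratum assigned to calibration with
  largest-remainder quota allocation, so 240 retained samples always split
  160/80.
* **Scale comparison.** The per-preprocessing table reports both the
  in-sample R²c and the cross-validated R²cv, and the best label is chosen
  by R²cv: with 160 calibration samples and 2151 predictors the in-sample
  R²c saturates near 1 for every preprocessing, so only the
  cross-validated figure can rank them. RPD is reported both as
  S_D/RMSECV (its defining form here) and as S_D/RMSEP (`rpdP`), labelled
  distinctly.
* **Region experiment.** Both arms (RSF, FSF) share one split and one
  transformed matrix — the best-scale CWT coefficients from the scale
  comparison; selection-then-regression differs only in the candidate
  mask. Because the Gaus1 wavelet is odd, coefficients cross zero exactly
  at an absorption centre and band-centre *recovery* is instead assessed
  on SNV spectra, where the centre carries maximal depth.

## Problem sizes

The shipped experiments use the default study conditions throughout: four
groups × 60 leaves (240 spectra) per dataset, day 30, and 20 seeded
replicate datasets for the stochastic claims (feature-fusion advantage and
mid-scale optimum). These sizes mirror the sampling design the generator
emulates and keep a full replicate set comfortably within a desktop run.

## Known limitations

* The generator's linear feature model means PLSR is close to the true
  functional form; SVR's nonlinearity buys nothing here, consistent with
  PLSR outperforming SVR in the comparable literature, but the package
  cannot evidence the reverse situation.
* Fv/Fm enters the spectra with tiny relative variance (it is a ratio
  pinned near 0.8), so its red-region features are intrinsically weak; the
  red-vs-fused contrast the pipeline exposes is partly a consequence of
  that biology-driven design choice.
* Edge-affected wavelet coefficients are flagged but not excluded from
  modelling; at coarse scales every band is edge-affected and the flag is
  purely informational.
* `splitDataset()` stratifies on the target variable only; no
  Kennard–Stone or leverage-based split is provided.
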