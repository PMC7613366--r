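---
title: "Estimating heavy-metal content in grapevine leaves from reflectance spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating heavy-metal content in grapevine leaves from reflectance spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitispec)
```

## The problem

Heavy metals absorbed by grapevines perturb pigment content, cell structure
and water relations; each of these leaves a trace in the leaf reflectance
spectrum. Visible reflectance (350–700 nm) responds to chlorophyll and
carotenoid loss, the red edge (680–750 nm) shifts with chlorophyll and
stress, near-infrared reflectance (700–1300 nm) tracks mesophyll structure,
and the mid-infrared (1300–2500 nm) tracks water content. `vitispec` builds
regression models that invert this relationship: given a leaf (or
pot-averaged) spectrum, predict the concentration of Cu, Zn, Pb, Cr or Cd
in the leaf tissue in mg/kg dry weight.

Because the package is developed and tested without access to a deposited
field dataset, it includes a first-class synthetic generator that emulates
the dosing experiment the analysis is designed for. Everything downstream
of data acquisition — index computation, scaling, splitting, PLS selection,
MLR/SVR modelling, diagnostics — is the same code a user would run on real
spectrometer exports.

## Data model

A `wavelength_grid` is an ordered, uniformly spaced set of channel centres;
the canonical grid is 350–2500 nm at 1 nm (2151 channels), and all I/O
(two-column text exports, wide CSV libraries) is linearly interpolated onto
it. Interpolation never extrapolates, duplicate wavelengths in inputs (as
produced by detector-seam overlap) are averaged with a warning, and
reflectance up to 0.05 outside [0, 1] is clipped with a warning while larger
excursions are rejected — small negative or above-unity values are routine
instrument noise, larger ones indicate a calibration fault.

Spectral regions are the conventional closed intervals VIS 350–700,
RDE 680–750, NIR 700–1300 and MIR 1300–2500 nm. Because the conventional
intervals overlap, a wavelength can belong to several regions; a unique
*primary* region is assigned by the precedence RDE > VIS > NIR > MIR. The
red edge wins because it is the narrowest and physiologically most specific
interval; per-region tallies of selected wavelengths would otherwise be
ambiguous at boundary channels.

The modelling unit is the pot: leaf spectra are averaged channel-wise to one
spectrum per pot before feature computation, matching how concentrations are
assayed (all leaves of a pot are pooled, dried and digested together).
A configuration switch could in principle model at leaf level, but
concentrations exist only at pot granularity, so pot level is the default
and the only supported mode.

## The synthetic dosing experiment

`default_design()` reproduces the experiment's arithmetic: five metals, four
stressed levels (1–4 × MAL in irrigation water), four replicate pots per
metal × level cell, and one *shared* control group of four pots, giving
4 + 5 × 4 × 4 = 84 pots and, at five leaves per pot, 420 leaf spectra. A
design with per-metal controls would need 100 pots; sharing one control
group across metals is the economical layout that keeps the experiment at
84 pots with four replicates throughout, so it is the default, with
`control_shared = FALSE` available. The MAL metadata carry the
irrigation-water standard values Cu 200, Zn 2000, Pb 100, Cd 10 µg/L; no
value is available for Cr, so its entry is `NA` and is deliberately left as
a documented gap — leaf concentrations are driven by the dose *multiplier*,
not the water concentration, so nothing downstream needs it.

The healthy baseline spectrum is a parametric green-leaf shape (green peak
at 550 nm, logistic red edge at ~715 nm, NIR plateau, water-absorption dips
near 1200/1450/1940 nm, declining MIR tail). Only the qualitative shape
matters; it is not a radiative-transfer model.

Stress reshapes the baseline through two mechanisms, both monotone in dose
so that stressed mean spectra dominate healthy ones channel-wise by
construction:

* a broadband regional lift (defaults per unit dose: VIS/RDE 0.008,
  NIR 0.004, MIR 0.006 reflectance), representing the overall loss of
  absorption by pigments and water; and
* Gaussian bumps (default amplitude 0.012 per unit dose, width 10 nm) at
  the metal's *sensitive bands* — by default the wavelength sets the
  selection stage is expected to recover, e.g. {1373, 631, 744, 438} nm for
  Cd.

Pot-to-pot biological variability has two layers. A common lognormal
*uptake* factor (sigma 0.25) scales all of a pot's band responses together:
pots that take up more metal respond more strongly. An independent lognormal
per-band *jitter* (sigma 0.3) lets individual response mechanisms vary in
relative strength. When `uptake_coupling` is on (default), the measured
concentration of the pot's own metal is `baseline + slope × dose × uptake`:
chemistry and spectroscopy share the pot's realized uptake. This coupling is
what makes spectra informative about concentration *beyond* the nominal
dose ladder — without it, a model could do no better than predicting the
dose group mean — and it is why the per-wavelength correlogram peaks at the
sensitive bands rather than on their shoulders. The broadband lift tracks
the nominal dose (a coarse, saturating whole-leaf response), which keeps the
metal-specific bands the most concentration-informative channels, exactly
the premise of wavelength selection.

Concentration defaults (control baseline / slope per dose unit, mg/kg DW):
Cu 8/25, Zn 25/55, Pb 4/25, Cr 1.5/7, Cd 0.005/90. These were chosen once
to give control levels and stressed ranges plausible for leaf tissue and
test-set RMSE magnitudes in the tens of mg/kg; Cd's near-zero baseline
exercises the left-censoring path (its control pots sit below the 0.009
mg/kg detection limit). Assay noise is mean-preserving multiplicative
lognormal with CV 0.09, reflecting the sub-10% relative standard deviation
typical of graphite-furnace AAS after acid digestion; values under the
per-metal detection limits (Zn 0.008, Cu 0.025, Pb 0.01, Cr 0.04, Cd 0.009
mg/kg) are reported *at* the limit with a censoring flag, never as zero.
Spectral noise is smooth correlated noise (white noise convolved with a
50 nm Gaussian kernel, sd 0.01) plus extra white noise (sd 0.02) at
350–400 nm, where field spectra are notoriously unstable.

What the generator does *not* emulate: radiative-transfer leaf optics,
soil–plant transfer chemistry, temporal development over the seven-month
stress program, instrument-specific artifacts beyond the UV-blue noise, or
any nonlinearity in the dose–response. Tests passing on synthetic data
therefore demonstrate that the *pipeline* recovers structure it is designed
for, not that real vineyard spectra contain that structure.

## Spectral indices

`index_registry()` carries the 32 vegetation indices used as the second
feature track. Each is implemented in one fixed, documented algebraic form;
three of them deliberately differ from the most common literature usage:

* **mNDVI705** defaults to `(R750 + R705)/(R750 + R705 − 2·R445)` — a sum,
  not a difference, in the numerator. The conventional red-edge NDVI form
  is available via `index_registry(mndvi705 = "literature")`.
* **PRI2** is `1.5(R830 − R660)/(R830 − R660 + 0.5)`, a SAVI-like formula
  rather than a normalized difference.
* **SIPI** is `(R445 − R800)/(R680 − R800)`, algebraically equal to the
  conventional `(R800 − R445)/(R800 − R680)`.

Window notations such as R960–990 (in RATIO975 and RATIO975_2) are
arithmetic means over the inclusive window on the 1 nm grid — the standard
reading of band-window notation.
Division by zero yields a flagged non-finite value rather than an error, so
a degenerate spectrum cannot silently crash a batch run; `compute_feature_table()`
returns the flags alongside the values.

## Scaling and splitting

All variables are min–max scaled to [0, 1]. By default scalers are fitted on
the *training* set only and applied to the test set (test values may leave
[0, 1]); fitting on the pooled data before splitting leaks test-range information
and is available behind `scale_before_split = TRUE` for comparison with
analyses that scale first. A constant variable scales to
all-zeros with a warning rather than dividing by zero. The 70/30 split takes
`round(0.7 n)` training samples, stratified over treatment cells with
largest-remainder allocation so the total is exact; strata smaller than two
fall back to unstratified sampling with a warning. RMSE reported in mg/kg is
obtained by inverting the concentration scaler, which for min–max scaling is
exactly the scaled RMSE times the fitted range; both scaled and original-unit
RMSE are always reported because unit conventions vary across studies and a
single unit is easy to misread.

## PLS1 feature selection

`fit_pls1()` is classical NIPALS with one response: per component the weight
vector is `w ∝ X'y` (unit norm), scores `t = Xw`, loadings `p = X't/(t't)`,
`q = y't/(t't)`, then `X` and `y` are deflated. Inputs are mean-centred
internally even though they are already 0–1 scaled — centring is part of the
NIPALS contract, not a preprocessing choice. Regression coefficients on the
input scale are `B = W(P'W)⁻¹q`. If the residual covariance collapses before
the requested component count (relative norm below 1e−12), extraction stops
with a warning rather than manufacturing numerically meaningless
components.

The component count is chosen by v-fold (default 10) cross-validated RMSE
over 1..k_max with a seeded fold assignment, taking the global minimum and
breaking ties toward fewer components. The per-fold RMSE spread is reported
as a standard error so callers can see whether the minimum is meaningful;
the selection rule itself stays the plain global minimum, the simplest
defensible criterion.

"Maximum factor loading" selection reads the X-loading vector `p` (the
natural meaning of *loading*); a switch to weights `w` exists because the
two are used interchangeably in much of the applied chemometrics
literature. Per component, in order, the
variable with the largest |loading| is selected; a variable already selected
falls through to the runner-up, so k components yield k distinct variables.
Selected wavelengths are annotated with their primary spectral region.

Two independent oracles pin the implementation down in the tests: PLS1
predictions with k components must equal the projection of y onto the
Krylov subspace span{X'y, (X'X)X'y, …} (computed by brute force with QR
orthogonalisation), and at full rank they must equal ordinary least
squares.

## Regression models and diagnostics

**MLR.** Forward selection adds, at each step, the candidate with the
largest R² increase (equivalently the largest RSS drop, evaluated with
partial F-tests via `add1`) provided its p-value is below `alpha_enter`
(default 0.05), then refits the final model by OLS. An exact duplicate of a
selected predictor has partial F = 0 and can never enter. Diagnostics:
Durbin–Watson `d = Σ(eₜ − eₜ₋₁)²/Σeₜ²` on residuals — the statistic needs
an observation ordering, and dataset row order is the recorded
convention — VIFs `1/(1 − R²ⱼ)` from auxiliary regressions, and the
overall F-test p-value ("significance of regression" is read as the overall
F-test). The validity gates are d ∈ [1.5, 2.5], all VIF < 10, p < 0.05;
models failing a gate are reported with flags, never suppressed, so a
violated assumption is visible instead of silently discarding the model.

**SVR.** "Regression SVM type 1" is read as ε-SVR (cost-parameterised,
`e1071::svm`). The default tuning grid covers the four kernels with cost
{0.1, 1, 10, 100}, ε {0.01, 0.1}, γ {0.05, 0.1, 0.25, 0.5, 1}, degree 2–11
(high polynomial degrees are retained because high-degree kernels do win
occasionally on small chemometric datasets) and offset {0, 1} — 928
configurations; these are declared defaults, adjustable through the config.
Model
selection is by seeded v-fold (default 5) cross-validated RMSE with ties
broken by grid order; inputs are pre-scaled, so the internal
standardisation of `e1071` is disabled. A `svr_grid_small()` (linear + RBF,
coarse lattice) exists for quick runs and is used in most tests.

## Numerical and degenerate-input conventions

* Zero-variance response: PLS and MLR reject it; `R²` on a constant test
  set is `NA` with a warning (SST = 0).
* All-zero residuals leave Durbin–Watson undefined (`NA` with warning).
* Exactly collinear predictors give infinite VIF, which fails the validity
  gate rather than erroring.
* Ties in CV (component count, SVR configuration) resolve to the simpler /
  earlier candidate, deterministically.
* Every stochastic step (generator, splits, folds) takes an explicit seed;
  a run is reproducible bit-for-bit from its config, and written artifacts
  are stamped with the seed and a config fingerprint.

## Problem sizes used by the test suite

The suite exercises the full default design (84 pots / 420 spectra / 2151
channels) for the end-to-end checks, and reduced designs (one metal, 1–2
leaves per pot) for unit-level pipeline tests. The planted-band recovery
study uses one metal with 16 replicate pots per level, single-leaf pots,
narrow strong band responses (amplitude 0.08, width 5 nm, band jitter 0.8),
low spectral noise (sd 0.002, no UV noise) and a generous 20-component
budget, over 100 seeded replicates; the generous component count is
deliberate because band-aligned variance can split across several
components, and the selection claim is that the planted bands appear *among*
the selections. Most tests use `svr_grid_small()`; the acceptance script
runs the full grid for all five metals and both tracks, which takes a few
minutes on one core.

## Known limitations

* The generator's dose–response is linear and its noise Gaussian/lognormal;
  saturating uptake, interactions between metals, and leaf-position effects
  are not modelled.
* Censored concentrations are reported at the detection limit and used
  as-is by the models (the correlogram excludes them pairwise by default);
  no censored-likelihood estimator is provided.
* Detection limits are instrument-specific; if your assay differs from the
  graphite-furnace defaults, set them in `noise_model()` — they only affect
  which low-concentration measurements are censored.
* Per-region tallies of selected wavelengths follow the package's stated
  precedence rule; analyses using a different boundary convention will
  count differently.
* PLS2, VIP scores, sparse PLS, backward/stepwise MLR and neural-network
  baselines are out of scope.
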