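---
title: "Egg freshness from visible-NIR transmittance spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Egg freshness from visible-NIR transmittance spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovofresh)
```

## The measurement problem

Shell-egg freshness degrades in storage: the thick albumen thins, the
yolk flattens as its membrane weakens, and water and CO~2~ escape through
the shell pores. The destructive reference indices are the Haugh unit
`HU = 100 log10(h + 7.57 - 1.7 m^0.37)` (albumen height *h* in mm, egg
mass *m* in g — higher is fresher, with the AA/A grade boundary at 72,
taken boundary-inclusive here), the yolk index `YI = h/d` (yolk height
over diameter, dimensionless), and the weight-loss rate
`WR = 100 (W_org - W_tst) / W_org` in percent. Whole-egg visible-NIR
diffuse *transmittance* spectra (light through shell, albumen and yolk;
550–985 nm at a 0.21 nm increment, 2071 variables) carry chemical
signatures of the same degradation — C–H/O–H features for albumen
protein and water, N–H/O–H for water redistribution — and this package
implements the two standard analyses built on them:

* **qualitative**: can the storage day be classified from the spectrum?
  (PCA scores → linear discriminant analysis);
* **quantitative**: can HU, YI, WR be calibrated from the spectrum?
  (synergy-interval PLS with leave-one-out cross-validation).

The design emulated throughout is 7 storage days (1, 3, …, 13) × 15 eggs
per day = 105 samples per temperature regime, split 70/35 into
calibration and prediction by the deterministic every-third-sample rule
after a stable sort by (storage day, replicate) — giving 10/5 per day.

## Wavelength grids

Instrument software disagrees about whether the start point of a range
counts as a variable. Both conventions are supported explicitly in
`make_grid()`: `count_floor_steps` yields `floor((stop-start)/step)`
points (550–985 nm at 0.21 nm → 2071 variables) and `inclusive_points`
yields one more (4000–10000 cm^-1^ at 3.856 cm^-1^ → 1557 variables).
Supporting both rather than guessing one resolves the off-by-one
ambiguity between the two instrument axes the package mirrors.

## Pretreatments and leakage

Scatter artifacts — per-sample gain and offset from shell thickness,
positioning and source drift — are handled by three standard
pretreatments:

* **SNV**: per-spectrum centering/scaling with the *n−1* standard
  deviation (stated explicitly because both conventions circulate);
  removes any per-sample affine artifact exactly.
* **MSC**: per-spectrum OLS regression on a reference spectrum, then
  inversion of the fitted slope and offset. The reference is the
  **calibration-set mean only** and is reused for prediction rows, so no
  information leaks from the prediction set into the treatment.
* **Savitzky–Golay derivatives**: window 15 points, quadratic polynomial
  by default (a bare difference filter would amplify noise); the filter
  matrix comes from the `signal` package, whose endpoint filters fit the
  local polynomial at the edges so the output keeps the input length —
  important so that interval bookkeeping downstream is unaffected.
  Derivatives are scaled by the grid step (units: absorbance per nm).

Division of labour between the stages: the **first derivative** is the
default for the quantitative calibration (it removes baseline offsets
while keeping band shapes localized), while the **qualitative stage
defaults to SNV**. The reason is numerical: differentiation multiplies
the noisy detector-edge channels and, after smoothing, correlates them
into spurious high-variance directions that crowd the 13-component score
space; SNV removes the entire gain/offset artifact family without
touching the noise spectrum. Both stages accept any configured
pretreatment.

## PCA → LDA discrimination

PCA is computed by SVD of the column-centered calibration matrix (never
the covariance matrix), with each component's sign fixed so its
largest-magnitude loading is positive — score plots are then
reproducible across BLAS implementations. The discriminant uses
class-specific means with a pooled within-class covariance, equal priors
(the design is balanced: 10 calibration eggs per day; empirical priors
are available), and a ridge of `1e-6 · trace/p` by default: 13 score
dimensions estimated from 70 samples across 7 classes is near-singular
territory. Ties in the discriminant go to the earlier class label. The
default of 13 components follows the depth at which room-temperature
discrimination is best in this setting; it is a plain argument
(`n_pcs`).

## NIPALS PLS and the interval search

With a single response, the NIPALS weight vector is exact in one pass
per latent variable, so no inner iteration (and no convergence
tolerance) is involved; extraction stops early if the deflated predictor
matrix loses rank (weight norm below `1e-12` relative to the response
norm). X and y are mean-centered; variance scaling is **not** applied by
default — derivatives/SNV already equalize scales — but `scale = TRUE`
exposes autoscaling. The sequential model is collapsed into a regression
vector `B_k = W_k (P_k' W_k)^{-1} q_k`, retained for every intermediate
depth so one fit scores all model sizes.

"Full cross-validation" is implemented as leave-one-out with fold-level
re-centering (the held-out sample contributes nothing to the fold
model). The chosen depth is the RMSECV argmin with ties broken toward
fewer latent variables. These kernels are compiled (RcppArmadillo)
because the interval search multiplies them by thousands of
combinations.

`sipls()` partitions the axis into equidistant intervals
(remainder-first: with `n mod k = r`, the first `r` intervals get the
extra variable — any balanced rule is admissible, one is fixed for
reproducibility; 2071 variables in 25 intervals → 21×83 + 4×82),
enumerates all 2- and 3-interval combinations (C(25,2)+C(25,3) = 2600 by
default; sizes configurable), concatenates each combination's columns,
and scores it by LOO RMSECV at 1–15 latent variables (cap configurable;
per-combination the depth is additionally limited by fold rank). The
global winner is deterministic: lowest RMSECV, then fewer latent
variables, then the lexicographically smallest combination.
Pretreatments are applied to the **full spectrum before** column
subsetting so derivative windows never straddle interval edges.
Evaluation refits on the winning columns and reports RMSEP and the
prediction-set Pearson correlation R(t).

## What the generator emulates

`generate_dataset()` draws, per egg, the three freshness indices from
normal distributions whose per-day means and sds are the package's
embedded reference trajectories for the two regimes — at 25 °C the
indices trend strongly (weight loss grows ~28-fold over 13 days), at
4 °C the Haugh unit and yolk index wander irregularly while weight loss
creeps. On top of that:

* **Latent vs measured indices.** The within-day spread is split into a
  latent biological part and destructive-measurement error (`bio_frac`,
  defaults HU 0.4, YI 0.5, WR 1.0): a 1 mg balance measures mass
  essentially exactly, while albumen-height gauges and hand calipers
  dominate the error of HU and YI. Spectra couple to the **latent**
  values (the photons interrogate the egg, not the caliper); the
  destructive table reports the measured values, whose total sd equals
  the trajectory sd. This is what lets a spectral classifier beat a
  classifier built on the destructive measurements themselves, as
  observed with real eggs.
* **Bands.** Three Gaussian absorption bands at 665, 760 and 930 nm
  (inside the informative 650–777 and 899–965 nm windows) with
  amplitudes linear in the standardized indices: HU → 665 nm,
  WR → 760 nm, YI → 930 nm, couplings 0.20/0.12/0.20 AU per
  standardized unit. Weight loss enters on the **log scale**: it spans
  a 28-fold range with level-proportional within-day sds, so the log is
  both the variance-stabilizing and the Beer–Lambert-consistent choice.
  The standardization constants are fixed (derived once from the
  room-temperature trajectory) and shared by both regimes — the
  spectrum responds to absolute chemistry, not to the regime label.
* **Artifacts.** Per-sample lognormal gain (sdlog 0.06) and normal
  offset (sd 0.15 AU) — exactly the family SNV/MSC remove; white channel
  noise 0.005 AU inflated ~41× toward the grid edges (CCD sensitivity
  roll-off), which is what makes wavelength-interval selection pay off
  over full-spectrum PLS; and twelve interferent bands (shell-pigment
  structure crowding 550–630 nm, minor composition variability
  elsewhere) with per-egg random amplitudes, placed **off** the
  informative bands — their joint rank is a burden a full-spectrum
  calibration must deflate latent variable by latent variable, while the
  discriminant absorbs them into its within-class covariance.
* **Consistency.** The destructive table is back-solved from the drawn
  measured indices (mass drawn around 60 g; stored mass from WR; albumen
  height by inverting the HU formula; yolk height from YI at a drawn
  diameter), so applying the index formulas to the emitted table
  reproduces the drawn values to machine precision. One seed drives
  every draw and the caller's RNG state is restored afterwards.

**What it does not emulate.** Real spectra reflect day-correlated
chemistry beyond the three indices (e.g. protein conformational change);
in the generator the spectral information about storage day is, by
construction, bounded by the information in the three index draws. Two
consequences, documented deliberately: room-temperature discrimination
saturates in the low-to-mid 80s% rather than the mid-90s% achievable
with real eggs (the adjacent days 3/5/7 differ by fractions of their
printed within-day spreads in every index); and refrigerated weight loss
remains spectrally predictable (the balance measures it exactly and its
4 °C trend is regular), so the refrigerated weight-loss calibration does
not collapse the way it does with real eggs. Passing tests therefore
certify the pipeline's mechanics and the qualitative regime gap, not
real-instrument accuracy levels.

## Problem sizes used in tests

The shipped checks run the full 105-sample design on a grid thinned to
399 variables (550–985 nm at 1.09 nm), 10 intervals with 2- and
3-interval combinations, leave-one-out cross-validation up to 10 latent
variables, and seed sweeps of 10–20 replicates — sizes chosen so the
whole suite exercises every stage end-to-end in well under a minute per
sweep while keeping the interval search genuinely combinatorial.

## Known limitations

* Single-response PLS1 only (each index is calibrated separately); no
  PLS2, no kernel variants.
* The interval search is exhaustive over 2–3-interval combinations, as
  specified; no genetic/backward selection.
* The simulator's baseline shape and absolute absorbance levels are
  plausible but uncalibrated to any instrument; only relative structure
  matters to the pipeline.
* The grade rule covers the AA/A boundary only.
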