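---
title: "Digestion kinetics and eGI prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digestion kinetics and eGI prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gikit)
library(tibble)
```

This vignette explains what `gikit` computes and why: the assay arithmetic,
the kinetic models, the model-selection and fitting choices, the
calibration statistics, and what the synthetic-data generator does and does
not emulate.

## From absorbance to digestogram

A reducing-sugar assay (PAHBAH, maltose standard) reports an absorbance
difference ΔA per aliquot. The conversion chain in
`absorbance_to_percent_digested()` is:

1. ΔA_sample / ΔA_standard × (standard concentration) → maltose
   concentration in the aliquot (mmol/L);
2. × aliquot volume (default 100 µL) → mmol of maltose assayed;
3. × 342 mg/mmol → maltose mass; × dilution factor → maltose mass released
   in the whole digestion vessel;
4. × 324/342 (two anhydroglucose units per maltose) → starch-equivalent
   mass; ÷ starch loaded × 100 → percent starch digested.

`absorbance_to_normalized_reducing_sugar()` stops at step 3 and divides by
the total available carbohydrate mass instead — the basis on which the
calibration predictor (AUCR180) is defined. For identical readings the two
bases differ by the fixed factor starch_mass/(carb_mass × 324/342), which
the tests verify numerically.

**Dilution factors.** The protocol defaults (2500 for INFOGEST, 750 for
the single-enzyme protocols) reproduce the computational multiples
conventionally printed with these assays (50 × 50 and 5 × 150). They are
not consistent with the nominal vessel volumes (50 mL and 18 mL against a
0.2 mL quenched aliquot would give 250 and 90). We keep the printed
multiples as defaults so existing results can be reproduced, expose
`dilution_factor` as a required, overridable configuration value, and warn
whenever a supplied vessel volume disagrees with the factor in use. For
the same reason the assayed `aliquot_volume_uL` (100 µL by convention,
although 200 µL is quenched) is configuration, not a constant.

Percent-digested values above 100 % occur with real assay noise near
complete digestion; they are retained and flagged, never clipped — clipping
would bias every downstream fit. Values above 110 % are rejected as data
errors.

## Kinetic models

Starch digestion at saturating enzyme concentrations is empirically
first-order in the remaining digestible substrate. The single-kinetics
(SK) model is

$$C_t = C_0 + (C_\infty - C_0)\,(1 - e^{-kt})$$

with `C0` the digested amount at t = 0, `C∞` the plateau (no digestible
substrate left) and `k` (min⁻¹) the rate coefficient. Foods with several
substrate pools (e.g. rapidly and slowly digestible starch) follow the
combined parallel-and-sequential (CPS) model: a sum of first-order
fractions, each with its own amplitude `C∞_j`, rate `k_j` and onset time
`t_jstart` (the first fixed at 0, later ones free). `fit_cps()` with one
fraction reduces exactly to `fit_sk()`.

Note the bookkeeping convention, which follows how the two models are
conventionally written: the SK `c_inf` is the *asymptote* of the curve
(`c_inf ≥ c0`), while each CPS fraction's `c_inf` is the *amplitude* added
on top of `C0`. `predict()` and `auc_analytic()` are aware of the
distinction.

### LOS analysis and fraction counting

The logarithm-of-slope (LOS) transform linearizes first-order kinetics:

$$\ln\frac{dC_t}{dt} = \ln\!\big(k\,(C_\infty - C_0)\big) - kt$$

`los_transform()` estimates the derivative by finite differences between
consecutive timepoints and places each log-slope at the interval midpoint,
which minimizes finite-difference bias for exponentials (on a grid of
spacing Δ the points lie on the exact line shifted by the constant
ln(sinh(kΔ/2)/(kΔ/2)) — the tests check this closed form). Non-positive
increments, common near the plateau where noise exceeds the signal, have
no defined logarithm; they are dropped and counted (`n_dropped`) rather
than imputed.

`count_fractions()` makes the usual by-eye judgement — "is the LOS plot one
straight line or two?" — reproducible. It enumerates all contiguous
segmentations with at least 3 points per segment (breakpoints on observed
midpoints), requires every segment slope to be negative, and selects the
segment count by BIC on the LOS residuals, ties toward fewer segments.
Two further admissibility constraints reflect what a distinct digestible
fraction means physically: segment slopes must be ordered steepest-first
(the rapidly digestible pool dominates the early derivative), and
consecutive decay rates must differ by at least `min_rate_ratio`
(default 3). Without the separation requirement, BIC alone splits noisy
single-fraction LOS plots — whose late points have strongly inflated
variance, since they are logs of small noisy increments — into two
segments far too often; fractions closer than ~3-fold in rate are not
resolvable as distinct linear stretches in plots of this length anyway,
and the discrimination the package promises (≥95 % correct at assay noise
SD 0.3) targets well-separated pools (rate ratio ≥ 5, onset ≥ 3 sampling
intervals). With fewer than 4 LOS points, or when no admissible
multi-segment candidate exists, the count falls back to one fraction with
a message.

### Fitting

Both fitters use bounded Levenberg–Marquardt via `minpack.lm::nls.lm` on
an explicit residual function. (The formula-level `nlsLM` wrapper is
avoided deliberately: it reconstructs an `nls` object after optimization
and fails with a spurious "singular gradient" error when started at or
near the optimum — exactly the noiseless-recovery case.)

- Parameterization: `c0 + dc(1 − e^{−kt})` with `dc = C∞ − C0 ≥ 0`, so the
  `C∞ ≥ C0` constraint becomes a simple box bound.
- Bounds: `k ∈ (0, 10]` min⁻¹, `C0 ∈ [0, max(value)]`,
  amplitudes `∈ [0, 3·max(value)]`, onset times inside the observed range.
- Initialization: `C0` from the first observation, `C∞` from the maximum,
  `k` from the single-segment LOS slope when obtainable (else 0.02 min⁻¹).
  If the default start does not converge, two more starts spanning a
  10-fold range of `k` are tried. CPS onset times are multi-started over
  the interior observed timepoints, which makes the non-smooth onset
  parameter reliably identifiable on the coarse single-enzyme schedule.
- Convergence tolerances `ftol = ptol = 1e-12` give noiseless parameter
  recovery to ~1e-9 relative; failures never raise — the best attempt is
  returned with `converged = FALSE` so a pipeline over many replicates
  continues, logging the fact.

`fit_kinetics()` fits each replicate independently by default, so the
replicate spread of the AUC can be propagated into prediction SDs;
`pool_replicates = TRUE` pools the points instead. Duplicate measurements
are typical in this assay, hence both modes.

## AUC summaries and calibration

`auc_analytic()` integrates the fitted curve in closed form:
`C∞·T − (C∞ − C0)(1 − e^{−kT})/k` for SK, and the analogous per-fraction
terms from each onset for CPS. Computing AUC from the *fitted* curve
rather than the raw points is deliberate: it permits a 180-min horizon
from the 120-min INFOGEST schedule (extrapolation along the fitted
plateau), and it decouples the summary from the sampling grid.
`auc_trapezoid()` is the raw-data cross-check (they agree to 0.01 % on
densely sampled exact curves) and refuses to extrapolate.

`correlation_screen()` reports Pearson r against GI and GL per candidate
parameter with two-sided t tests on n − 2 degrees of freedom, starred at
p < 0.05 (*) and p < 0.01 (**). Raw p-values are the default — matching
how such screening tables are conventionally reported — with an optional
Holm adjustment (`p_adjust = "holm"`).

`fit_calibration()` is ordinary least squares of GI on AUCR180.
`predict_egi()` applies the line and attaches the standard error for a
*new observation*, `s·sqrt(1 + 1/n + (x − x̄)²/S_xx)`, combined in
quadrature with the replicate-propagated `b·sd(AUCR180)` when supplied.
How published eGI ± SD values were originally derived is typically not
stated; this prediction-interval construction is our documented choice,
not a reconstruction. `error_rate()` is the validation statistic
|eGI − GI|/GI × 100, reported to 2 decimals like GI, GL and eGI
themselves (correlations to 3).

## The synthetic-data generator

`simulate_digestogram()` evaluates the SK/CPS forward model on the
INFOGEST intestinal (0–120 min) or single-enzyme (5–240 min) sampling
schedule and adds i.i.d. homoscedastic Gaussian noise, truncated at zero.
Duplicate replicates are the default, matching usual assay practice. The
noise model is the simplest consistent with duplicate-measurement spreads;
sd 0.3 (in normalized reducing-sugar units) is the default study
condition.

`simulate_absorbance_series()` inverts the conversion chain exactly, so
the raw-ingestion path can be tested against known truth.

`simulate_calibration_study()` draws AUCR180 targets uniformly in
500–3500 units·min (the realistic range for low-to-moderate-GI biscuits on
this basis), fixes `C0 = 0`, draws `k` uniformly in 0.005–0.05 min⁻¹ and
*solves* `C∞` so each curve's analytic 180-min AUC equals its target —
giving exact control of the calibration predictor — then assigns
GI = 1.834 + 0.009·AUCR180 + N(0, 1) by default. Eight samples with
duplicate digestograms mirror a realistic calibration panel. All
generators are bit-reproducible given a seed.

What the generator does *not* emulate: heteroscedastic or multiplicative
assay error, inter-batch and inter-manufacturer variation, protein/fat
matrix effects on enzyme access, particle-size distributions, and any
deviation of true digestion from first-order form. Passing recovery tests
on synthetic data therefore demonstrates that the estimation machinery is
correct and self-consistent — not that the first-order model or the linear
GI law is adequate for any particular real food.

## Problem sizes and determinism

The test suite and the acceptance script use: 200 seeded realizations for
SK noise-bias checks; 100 + 100 seeded curves for the SK/CPS
discrimination suite; 500 seeded studies (8 samples × 2 replicates each)
for end-to-end calibration recovery; 0.001-min grids for trapezoid-oracle
AUC comparisons; 1-min grids for LOS linearity. These sizes give
Monte-Carlo standard errors well below the tolerances being asserted.
Every stochastic step is seeded, and identically seeded pipeline runs
produce byte-identical rendered tables.

## Known limitations

- Fraction counting is limited in practice by the sampling schedule: with
  10 points (9 LOS increments at most), at most two fractions are
  identifiable, and onsets earlier than the third timepoint are poorly
  resolved.
- The CPS onset parameter makes the objective non-smooth; the multi-start
  grid over observed times handles the schedules used here but very dense
  schedules would warrant a dedicated breakpoint search.
- Calibrations are protocol- and basis-specific; applying a pancreatin
  calibration to INFOGEST-derived AUCs is not meaningful, and the package
  stores protocol/basis labels with each model for that reason.
- GL is computed from GI and total carbohydrate content; available-
  carbohydrate corrections (fibre, resistant starch) are the user's
  responsibility upstream.
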