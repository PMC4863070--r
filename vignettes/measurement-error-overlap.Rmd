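---
title: "Modelling differential measurement error in indirect calorimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling differential measurement error in indirect calorimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vo2overlap)
```

## The model

The classical measurement-error model `W = X + U` assumes the error `U` is
independent of the true value `X`. Gas-exchange indirect calorimetry
violates this: the day-to-day error of a VO₂ measurement depends on the gas
flow itself — *differential* measurement error, `W = X + X·U_X` in its
general multiplicative form. vo2overlap works with the operative version of
this idea: an observed measure at level μ (L/min) is modelled as

$$W \sim \mathrm{Normal}\big(\mu,\ \sigma_{\text{device}}(\mu)\big),$$

where σ(μ) is a low-order polynomial (order ≤ 3) fit to two-day test–retest
data — each data point being the mean and standard deviation of one
subject-workload pair measured on two different days. Two measures then give
two normal densities, and their **overlapping coefficient**
$\mathrm{OVL} = \int \min(f_1, f_2)\,dx$ is reported as the probability that
they are the same measure. Because the model is built from *between-day*
pairs, it captures combined biological and instrument variability; applying
it to two measures taken within one session will be conservative.

Assumptions worth stating plainly: normality of the day-to-day error at each
flow level; a smooth polynomial dependence of σ on μ; and no systematic
drift between days (the two days are exchangeable draws).

## Computing the overlap

`ovl_normal()` is analytic. With equal standard deviations the densities
cross once and $\mathrm{OVL} = 2\Phi(-|\mu_1-\mu_2|/2\sigma)$; this branch
triggers when |σ₁−σ₂| ≤ 1e−12·max(σ₁,σ₂), where the two-crossing geometry
degenerates. Otherwise equating log-densities gives a quadratic whose two
roots are the crossing points, and the OVL is the sum over the three
resulting segments of the CDF mass of the pointwise-smaller density. Two
numerical details matter:

* which density is smaller on a segment is decided by evaluating both at an
  interior point **on the log scale** — raw densities underflow to an
  ambiguous 0 = 0 tie when the distributions are many σ apart;
* arguments are put into a canonical order first, so the result is
  bitwise-identical under swapping the two distributions.

`ovl_numeric()` — trapezoidal integration of min(f₁, f₂) at step 1e−4 over
both means ± 8·max(σ) — exists purely as an independent oracle; the suite
checks agreement to 1e−5 over randomized parameter sweeps including the
equal-σ branch.

## Where the shipped calibrations come from

The regressions behind the original ParvoMedics 2400 TrueOne and Douglas-bag
error models were fit to raw two-day data that was never published; only
worked-example overlap values were printed. The shipped defaults are
therefore **recovered by inversion**, which is the central engineering
decision of this package:

* **ParvoMedics — linear.** Only two same-system printed examples exist
  (1.5 vs 1.7 → 0.103; 3.3 vs 3.5 → 0.358). Two constraints determine
  exactly two parameters, so σ_P(μ) = c₀ + c₁μ is solved as a square
  root-finding problem through the analytic OVL (Levenberg–Marquardt,
  parameter tolerance 1e−15); residuals at the solution are ~1e−15. A cubic
  here would be wildly underdetermined — the linear model is the most that
  the printed evidence supports.
* **Douglas bag — cubic.** Five printed constraints are available: two
  same-system worked examples (0.172, 0.467) plus three distinct
  baseline-vs-follow-up pairs from a published endurance-training
  re-analysis (2.19 vs 2.48/2.57/2.51 L/min → 20.9%, 10.5%, 16.8%),
  attributed to the Douglas bag as the assumed gold-standard method. Five
  constraints over four parameters are fit by least squares (objective:
  squared OVL residuals), initialized from the equal-variance inversion
  `solve_sigma_equal()` at each constraint's μ midpoint followed by a
  polynomial fit through those points. The duplicated 9-month pair
  (identical to the 3-month one) enters once. The converged fit nearly
  interpolates: its RMSE over the five constraints is ~3e−5, far inside the
  0.03 acceptance bound.
* **Holdout.** The one cross-system example (3.0 Douglas vs 3.3 ParvoMedics
  → 0.231) is never used in fitting. The recovered calibrations predict
  0.216 for it — an out-of-sample error of ~0.015, which is the honest scale
  of the recovery's uncertainty.

The recovery is deterministic — fixed constraint table
(`worked_example_constraints()`), fixed initialization, fixed tolerances, no
randomness — so every session reproduces identical coefficients.
`default_registry()` caches the one-time solve.

Known limitation: the recovered Douglas cubic has a negative leading
coefficient and its σ(μ) dips slightly for μ above ≈ 3.2 L/min. The
qualitative behaviour the worked examples demonstrate — larger overlap (more
forgiving error) at higher flows — holds at every printed comparison point,
but strict monotonicity of σ over the whole calibrated range is not
guaranteed by the inversion and should not be assumed. The defaults are
faithful to the printed numbers, not a re-derivation of the original raw-data
regressions.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 0.10 | similarity probability below which two measures are called "truly different"; equality counts as "not distinguishable" |
| `valid_range` | [1.0, 4.0] L/min | μ interval a calibration is trusted on; modestly extends the printed example span (1.5–3.5) |
| hard envelope | [0.3, 6.0] L/min | physiologic VO₂ range; outside `valid_range` but inside the envelope the package warns and extrapolates, outside it refuses |
| `order` | 3 | polynomial order for `fit_calibration()` (1–3) |
| `unbiased` | `FALSE` | c₄(2) correction in `fit_calibration()` (below) |

All values are strictly L/min; body-mass-normalized data (mL/kg/min) belongs
in hypothesis testing, not here. Unknown device labels fail loudly with the
list of known devices — only an *omitted* system argument defaults to the
ParvoMedics cart.

## Fitting new calibrations, and the pair-SD bias

`fit_calibration()` implements the stated procedure: ordinary least squares
of the pair SD on powers of the pair mean. One statistical subtlety is worth
knowing. The SD of a two-value pair, $|d_1-d_2|/\sqrt{2}$ (n−1 denominator),
has expectation $c_4(2)\,\sigma = \sqrt{2/\pi}\,\sigma \approx 0.798\,\sigma$,
so the raw regression estimates the *expected pair SD*, about 20% below the
error σ itself. `unbiased = TRUE` divides each pair SD by c₄(2) before the
regression, giving an unbiased estimate of σ(μ). The default remains
`FALSE` — the uncorrected regression is the procedure the shipped
calibrations' source describes, and on records constructed directly from a
known σ curve the uncorrected fit reproduces that curve exactly (to 1e−10 on
noiseless polynomial data, which the suite asserts). Use `unbiased = TRUE`
whenever the records are genuine two-day pairs and you want σ on the correct
scale.

## The synthetic protocol and what passing tests mean

`synthetic_protocol()` / `generate_test_retest()` emulate a two-day,
multi-workload calibration study: each of `n_subjects` is "measured" at each
workload on two days, with draws from Normal(X, σ_true(X)) truncated at zero
by resampling (an observed VO₂ cannot be ≤ 0; the truncation is a deliberate
deviation from a pure normal, negligible except at extreme σ). Defaults:
workloads 1.0–4.0 L/min in 0.5 steps (a typical incremental cycling grid)
and a gently increasing σ_true of realistic magnitude (≈ 3–6% coefficient of
variation, in line with published day-to-day reproducibility of metabolic
carts). Seeds are explicit and required; generation saves and restores the
caller's RNG state.

The generator captures flow-dependent error magnitude and between-day
sampling noise. It does **not** simulate training effects between days,
within-day autocorrelation, device drift, operator technique, or non-normal
error tails — so passing parameter-recovery tests demonstrate that the
fitting machinery works under the model's own assumptions, not that real
devices obey them.

On recovery precision: with 500 pairs over a 10-point workload grid, the
c₄-corrected cubic fit is unbiased, and across 20 seeded replicates the
*median* of the maximum pointwise relative error on the central 80% of the
design range stays below 10% — but its sampling spread is wide, so an
individual 500-pair calibration can miss 10% pointwise (the fixed-seed run
in the acceptance suite lands at 10.6%). Plan for ~10% curve uncertainty
from a study of this size; more subjects per workload tighten it as √n.

## Degenerate inputs and numerical choices

Zero-noise protocols are permitted (they collapse to exact pairs and are
used to test the zero-noise limit). Underdetermined fits (fewer records, or
fewer *distinct* μ values, than order + 1) raise an insufficient-data error
rather than a silent rank-deficient fit. A fitted or constructed σ(μ) that
is non-positive anywhere on its validity interval (checked on a 512-point
grid) is rejected at construction. Registry JSON serializes coefficients at
17 significant digits so write/read round-trips are exact. Batch vectors of
unequal length, empty inputs, and missing values are rejected, never
imputed.

## Scope

No hypothesis testing, confidence intervals, or clinically-meaningful-change
thresholds; no within-session comparisons; no non-normal or multivariate
error families; no mL/kg/min support. The calibration-fitting API is
variable-agnostic, so ventilation or VCO₂ calibrations can be fit from user
data, but none ship — no raw validation data for them has been published.
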