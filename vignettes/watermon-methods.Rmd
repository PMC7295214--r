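---
title: "Models and methods behind watermon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind watermon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(watermon)
```

`watermon` analyses long-running drinking-water compliance archives: for
each period (month or week) a number of samples tested and a number
positive for each microbial indicator (TC, EC, IE, SSRC), summarised as the
frequency of positive samples, alongside cumulative rainfall on the same
time index. This vignette is the package's own account of the models, the
parameters that matter, the numerical choices, and what the validation
suite does and does not establish.

## The data model

A `marker_series` is a gap-free (year, period-of-year) grid with counts,
frequencies and missingness flags; weeks use a fixed 52-week year (a 53rd
ISO week is folded into week 52) so that week-of-year indexing, the wet/dry
season split (wet November–April ≙ weeks 41–13 wrapping, dry May–September
≙ weeks 14–40), and the seasonal-mean forecaster are all total functions of
the period index. Missing periods are filled by
`impute_median_by_period()`: the median of the non-missing values sharing
the period-of-year. The rule is deliberately strict — if some
period-of-year has no donor at all the function stops rather than falling
back to a global median, because a week never observed carries no seasonal
information and silently smoothing over it would bias every seasonal stage
downstream.

The lagged covariate `cumulative_exposure(rain, L)` is the rainfall summed
over the L periods *strictly before* t. The window excludes the current
period because the covariate must be known before the target week is
observed for forecasting use; an inclusive window is available via
`include_current = TRUE` for sensitivity analyses.

## The synthetic generator as study design

No multi-decade monitoring archive is distributed with the package, so the
generator *is* the study population, and its defaults are fixed once:

* **Rainfall.** Period means follow `((1 + cos(2π(p − peak)/P))/2)^a`
  scaled to an expected 1600 mm/year, peak January, exponent `a = 2`,
  multiplicative gamma noise with shape 6 (CV ≈ 41% per month). A plain
  raised cosine (a = 1) cannot simultaneously give January above 300 mm and
  June below 10 mm at a realistic annual total; the power profile
  reproduces both extremes, and `a = 0` degenerates to a flat profile for
  tests.
* **Contamination.** Per period,
  `p_t = plogis(b(t) + m(period) + β·(C_L(t) − E[C_L]))` with a
  piecewise-constant baseline `b(t)` shifted at the planted break months, a
  cosine period-of-year effect `m`, and the centred cumulative-rainfall
  term; positives are Binomial(n_tested, p_t). Centring the exposure keeps
  `b` interpretable as the level under typical antecedent rainfall — an
  uncentred term of realistic magnitude would push baselines far from the
  few-percent contamination range the defaults target. The 32-year monthly
  default plants three shifts (after ≈5, 19 and 26 years) through baseline
  levels 4.7%, 1.1%, 4.2% and 9.5%; weekly defaults use 20 samples/week
  (four sampling points a day, five days a week), monthly 85.
* **Markers.** `gen_monitoring()` simulates at the *sample* level: each
  tested sample is positive for marker m independently with that marker's
  probability, and TOTAL counts samples positive for ≥ 1 indicator. The
  TOTAL ≥ single-marker dominance and the TOTAL ≤ sum-of-markers overlap
  bound therefore hold by construction, not by assertion.
* **Missingness.** Bernoulli masking at 6.41% (monthly) / 18.69% (weekly).
  The pipeline uses an opt-in `ensure_donor` mode that redraws a mask which
  would blank *every* occurrence of some period-of-year — at 18.69% on a
  short weekly panel that event is common enough to matter, and the
  imputation rule (correctly) refuses it. The marginal masking rate is
  essentially unaffected.

What the generator does **not** emulate: spatial sampling structure,
cyclone-type extreme events, overdispersion beyond binomial (a beta-binomial
switch is a natural extension), serial dependence in the binomial noise
itself, and measurement-method changes. Passing recovery tests therefore
demonstrates that the estimators work when their model assumptions hold,
not that real archives satisfy those assumptions.

## Breakpoints

`optimal_breaks()` minimises the within-segment RSS exactly by the Bellman
recursion over the last break position, O(n²) per break via prefix sums of
x and x²; ties go to the earliest admissible break for determinism.
`select_num_breaks()` evaluates m = 0…m_max and minimises
BIC(m) = n log(RSSₘ/n) + (2m + 2) log n — the parameter count charges each
break date, each segment mean, and one variance. Minimum segment length
defaults to ⌊0.15 n⌋ (the common 15% trimming) and m_max to the most the
trimming allows, capped at 5.

Two numerical caveats. RSS(m) is non-increasing in m only when the
constraint set allows refining the m-break optimum; with tight trimming the
(m+1)-break problem need not contain any refinement, and a small RSS
increase is then legitimate, not a bug (the DP is verified against
exhaustive enumeration). Zero-RSS segmentations (noiseless staircases) are
handled by flooring RSS at the smallest positive double before the log;
ties still resolve to the smallest m.

Confidence intervals use a residual-resampling bootstrap (B = 199 in the
pipeline): residuals from the fitted step function are resampled with
replacement, breaks re-estimated at the selected m, and empirical 2.5/97.5%
quantiles taken per break, widened if needed to contain the point estimate.
This trades the asymptotic break-date distribution for a scheme that is
simple, testable at desk scale, and honest about simulation error; the
`ci_method` tag records it. Coverage at a 2-SD shift measures ≈ 85–95% in
the test suite, consistent with the known finite-sample optimism of
resampling intervals for discrete break dates.

## Periodicity

The test statistic is the periodogram intensity at the Fourier frequency
nearest 1/P, with the series trimmed to whole cycles so the annual line is
an exact Fourier frequency (no leakage); the null is generated by uniform
random permutations of the centred series, and the add-one p-value
`(1 + #{I* ≥ I})/(1 + B)` (B = 999 by default, resolution 0.001) is never
zero. Centring makes the decision invariant to shifting and rescaling. No
multiple-testing correction is applied across the marker × regime table —
the p-values are reported raw, and blocks shorter than two full cycles are
flagged and left untested rather than dropped.

## Clustering

Active variables are the four single-marker frequencies only; TOTAL is
excluded from the metric (it is a deterministic near-combination of the
others) and rainfall is external — both enter only the cluster profiles.
Ward linkage runs on squared Euclidean distances, so merge heights equal
twice the increase in within-cluster sum of squares; the test suite checks
this against a greedy agglomeration recomputed from the definition. No
standardisation is applied by default since all four variables share the
unit "fraction of positive samples" (`standardize = TRUE` switches to
z-scores). Clusters are renumbered by decreasing size after cutting, so
"cluster 1" is always the dominant profile; supplementary-variable
permutation invariance is asserted by test, not just by construction.

## Lag models

The three-way comparison per marker is: (i) naive forecast — the mean of
the same week-of-year over all earlier years; (ii) ARIMA with no covariate;
(iii) ARIMA adjusted on C_L, L scanned over 1–10 weeks. Orders come from a
stepwise BIC search in the Hyndman–Khandakar style: d by repeated KPSS
tests (5% critical value 0.463, max d = 2), then (p, q, constant) moves of
±1 from starts (0,0), (1,0), (0,1), (2,2), accepting any BIC improvement,
p, q ≤ 5. The search runs once on the no-covariate training fit and the
orders are reused across lags, which keeps the ten per-lag BICs comparable
and the scan fast; `auto_per_lag = TRUE` re-selects per lag, and if the
shared order fails to converge for some lag the scan falls back to a fresh
stepwise search there rather than aborting.

"Cross-validation over the final two years" is operationalised as
rolling-origin one-step-ahead evaluation with parameters frozen at the
training fit: re-running the Kalman filter over the full series with all
coefficients fixed yields exactly those forecasts, so the implementation
refits `stats::arima` with `fixed = coef` and reads the one-step residuals
on the validation window. All three models are scored on the identical
window and targets, making the RMSE columns directly comparable.
Frequencies are modelled untransformed in [0, 1], matching the modelling
unit throughout the package; a logit transform is easy to apply upstream
for robustness checks.

The covariate's contribution is tested by a likelihood ratio with the
reduced model *refitted at the adjusted model's orders* — two independently
auto-selected models are not nested (the no-covariate BIC can even be
lower, as the EC rows of the demo show), so both BICs are reported but the
test uses the nested pair, χ²₁ on `max(0, 2ΔlogL)`. Residual whiteness uses
Ljung–Box with 10 lags and `fitdf = p + q`.

## Validation sizes and what they show

The acceptance suite runs, at fixed seeds: 200 random series (n ≤ 30,
m ≤ 3) for DP-vs-enumeration exactness; 100 null and 100 step series
(n = 120, 4-SD step) for selection calibration (≥ 90% zero-break, ≥ 95%
correct step within ±2); 500 white-noise and 200 SNR-1 cosine series for
the permutation test's size ([0.03, 0.07]) and power (> 0.9); 45
observations in 4 planted profiles for exact ARI-1 recovery; 50 weekly
panels (6 years, planted L\* = 4, β = 0.008 — twice the generator default,
the "strong effect" condition fixed in advance) for lag recovery within ±1
in ≥ 80% with the adjusted model beating both benchmarks on average; 500
null fits each for likelihood-ratio and Ljung–Box calibration; and a
two-run byte-identity check of the pipeline bundle. These sizes keep the
whole suite within a desk-scale run while leaving the binomial Monte-Carlo
error well inside each acceptance band.

## Known limitations

* Mean-shift breaks only; no breaks in regression coefficients, no
  heteroskedasticity-robust corrections.
* Non-seasonal ARIMA by default — seasonality is expected to enter through
  the rainfall covariate or to be removed upstream.
* The bootstrap break intervals are approximate; for shifts under ~1 SD
  they can be optimistic.
* The multiple-correspondence-analysis companion sometimes used alongside
  profile clustering is intentionally out of scope.
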