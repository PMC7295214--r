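# watermon

Time-series analysis of long-running microbial drinking-water monitoring
records.

Water utilities in low-income, climate-exposed cities accumulate decades of
weekly compliance samples: counts of samples tested and samples positive for
faecal-indicator bacteria — total coliforms (TC), *Escherichia coli* (EC),
intestinal enterococci (IE) and spores of sulfite-reducing clostridia
(SSRC). Such archives carry three questions that routine compliance
reporting never answers: *when* did the baseline contamination level shift
(infrastructure or watershed regime changes), *does contamination follow the
rainy season*, and *how much antecedent rainfall, accumulated over how many
weeks, best predicts next week's contamination*. `watermon` implements that
analysis chain for per-period positivity frequencies, plus a synthetic-data
generator with planted structure so every stage can be validated by
parameter recovery.

## Methods at the core

* **Multiple mean-shift breakpoints.** For a frequency series
  *y₁…yₙ*, the segmentation with *m* breaks minimises the within-segment
  residual sum of squares, found exactly by dynamic programming over
  admissible break placements (minimum segment length *h*, default
  ⌊0.15 n⌋). The number of breaks minimises
  BIC(m) = n·log(RSSₘ/n) + (2m + 2)·log n, and break-date 95% intervals come
  from a residual-resampling bootstrap.
* **Annual periodicity.** The periodogram intensity
  I(f) = |Σₜ yₜ e^(−2πi f t)|²/n at the Fourier frequency nearest 1/12
  (months) or 1/52 (weeks) is compared with its distribution over random
  permutations of the series; p = (1 + #{I* ≥ I}) / (1 + B).
* **Contamination profiles.** Monthly observations on the four markers are
  clustered by Ward's minimum-variance criterion on squared Euclidean
  distances; rainfall and total contamination are supplementary (profiled,
  never used in the distances).
* **Distributed-lag ARIMA.** The cumulative-rainfall covariate
  C_L(t) = Σ_{k=1..L} rain(t−k) is scanned over L = 1…10; for each L an
  ARIMA-X (orders by stepwise BIC search with KPSS differencing) is fitted
  on the training window and scored by rolling one-step-ahead RMSE over the
  final two years, against a naive week-of-year-mean benchmark and a
  no-covariate ARIMA. The covariate is tested by a nested likelihood ratio
  and residuals by a Ljung–Box portmanteau test.

## Worked example

Run the bundled end-to-end demonstration — a simulated 32-year monthly panel
(three planted regime shifts; wet-season month effect for TC and IE, none
for EC) and a 6-year weekly panel (planted cumulative-rainfall lags of 8, 5
and 4 weeks for TC, IE and SSRC; none for EC):

```r
library(watermon)
run_pipeline(pipeline_config(seed = 1), "reports")
```

`reports/breakpoints.csv` then holds, per marker, the BIC-selected break
dates with bootstrap intervals, e.g. (seed 1):

```
"SSRC",1,63,"1991(3)","1990(9)","1993(6)"
"SSRC",2,227,"2004(11)","2003(3)","2006(1)"
"SSRC",3,312,"2011(12)","2010(11)","2012(5)"
```

— SSRC recovers all three planted shifts (truth: months 60, 228, 314) with
the break date printed as year(month) and its 95% interval. In
`reports/lagscan.csv`:

```
"TC",8,-688.99,-630.48,1.3e-15,0.342,0.0582,0.0585,0.0671
"EC",6,-1051.41,-1055.99,0.383,0.914,0.0175,0.0191,0.0175
"SSRC",4,-611.19,-562.21,1.7e-13,0.442,0.0502,0.0539,0.0581
```

columns are marker, best lag (weeks), BIC of the adjusted and no-covariate
models, likelihood-ratio p, Ljung–Box p, then validation RMSE of the
adjusted, naive, and no-covariate models. TC and SSRC recover their planted
lags (8 and 4 weeks) with decisive likelihood ratios and the adjusted model
predicting best; for EC — simulated with no rainfall effect — the
no-covariate model has the lower BIC and the likelihood ratio is
non-significant, exactly the pattern the scan is built to expose.
`periodicity_pvalues.csv` shows the month effect significant in every regime
for TC (p = 0.001) and not for EC (p ≈ 0.4), and `cluster_profiles.csv`
separates high-rainfall/high-contamination months from dry low-contamination
ones.

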