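---
title: "Designing monitoring surveys with time-integrated station averages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing monitoring surveys with time-integrated station averages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optimon)
```

## The problem

A monitoring program that wants to detect a change of a few percent in an
environmental variable between two years cannot do it from raw
within-season observations: coastal time series are seasonal,
autocorrelated, and often skewed, so the variance of any single-occasion
estimate is enormous and the required sample sizes run into the hundreds or
thousands. optimon implements a design calculus built on a different
statistic: the *time-integrated station average*. Each station's irregular
seasonal series is collapsed into one time-weighted mean,

$$\bar{X} = \frac{\sum_i X_i\, w_i}{\sum_i w_i},$$

where the weight $w_i$ is the length of the interval reaching halfway to
the neighbouring sampling times (the period is extended by half a gap
beyond the first and last samples). Seasonal trend, autocorrelation and
non-normality are absorbed inside the integral; what remains is one number
per station, and the stations become approximately exchangeable, normally
distributed replicates. Their coefficient of variation,
$\mathrm{CV}\% = 100\,s/\bar{x}$, is typically several-fold smaller than
the spatial CV of any single-day snapshot or the temporal CV of any single
station — the pooling effect that makes precise inter-annual comparison
affordable.

## The model chain

The package chains four pieces of arithmetic, each exposed as plain
functions:

1. **Cast reduction** (`band_mean()`, `fit_extinction()`,
   `cast_summaries()`). Vertical sensor profiles are reduced to one scalar
   per station and occasion: the arithmetic mean over a closed surface
   depth band (default 0–3 m), and, for irradiance, the attenuation
   coefficient $k$ of $I_d = I_0 e^{-kd}$, fitted by ordinary least squares
   of $\log I$ on depth. The 1% light depth $-\ln(0.01)/k$
   (`euphotic_depth()`) indicates how much of the euphotic zone the band
   covers.

2. **Integration and variability** (`time_integrated_mean()`,
   `area_summary()`, `variability_table()`, `normality_check()`). Station
   series are integrated; the between-station CV% of the integrated means
   is the quantity the design runs on. `variability_table()` computes the
   contrasting per-occasion (spatial) and per-station (temporal) CVs, raw
   and log-transformed, that show what pooling buys.

3. **Sampling frequency** (`frequency_analysis()`, `min_frequency()`).
   Starting from a weekly pilot grid, the occasions are thinned to evenly
   spaced subsets and the area mean recomputed; the result is expressed as
   a percentage of the full-frequency reference. The lowest frequency
   whose mean stays within ±5% of the reference — with every intermediate
   frequency also passing (monotone acceptance) — becomes the
   surveys-per-year factor $N_\mathrm{time}$.

4. **Cost, precision, power** (`cost_model()`, `ci_percent()`,
   `budget_for_portfolio()`, `min_n_for_power()`, ...). The survey cost is
   linear,
   $$\mathrm{Cost} = N_\mathrm{time} N_\mathrm{space}
     \left[A/n + \textstyle\sum m_i\right] + B,$$
   with ship day cost $A$, stations per cruise day $n$, per-variable
   analysis costs $m_i$, and fixed overhead $B$. Precision follows
   $\mathrm{CI}\% = t \cdot \mathrm{CV}\% / \sqrt{N}$, which inverts into
   stations-for-precision, cost-for-precision and precision-from-budget.
   Power to detect a $\delta\%$ change between years uses the two-sided
   one-sample t test with standardized effect $d = \delta\% / \mathrm{CV}\%$
   and the noncentral t distribution (df $= n-1$, noncentrality
   $d\sqrt{n}$).

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| depth band | 0–3 m, closed | surface layer where seasonal variability concentrates; boundary samples included |
| t multiplier (`t_mode = "fixed"`) | 2.01 | two-sided 95% Student t multiplier at roughly 20 stations; keeps CI% a pure power law in N for planning. `"exact"` mode uses `qt(0.975, ceiling(N) - 1)` |
| frequency tolerance | ±5% | maximum acceptable drift of the thinned seasonal mean from the weekly reference |
| `alpha`, `beta` | 0.05, 0.2 | conventional significance and type-II rates; target power 0.8 |
| `deltas` | 5%, 10% | inter-annual changes worth detecting in most programs |
| cost constants | A=1, B=20, n=3, Σm=0.1, N_time=12 | worked example in relative units; replace with real costs and currency |
| `min_points` | 4 | fewest occasions for which a station's integral is still reported |

Design choices worth knowing about:

* **End-interval convention.** The integration period extends half a gap
  beyond the terminal samples. Any other convention breaks the property
  that equally spaced series integrate to their arithmetic mean, which the
  whole frequency-reduction analysis standardizes against. The
  equal-weight case is computed as `mean(values)` verbatim so the
  equivalence is exact in floating point, not just to rounding.
* **Sample SD uses n − 1** throughout; CV is reported as missing (never
  infinite) when the mean is zero.
* **Log transform is the natural log**; the log-scale grand mean is
  reported back-transformed (geometric mean). Base choice rescales
  log-scale CV magnitudes but not their patterns.
* **Monotone frequency acceptance.** A sparse schedule that passes below a
  failing denser one is not trusted: acceptance stops at the first failure
  walking down from the reference.
* **Sidedness.** The power analysis is two-sided; it is the convention
  that reproduces the reference sample-size tables this package is
  validated against, and the directional question ("did it change?") is
  two-sided in routine monitoring. Note that at $n = 2$ the t test has
  df = 1 and very little power regardless of effect size; sample-size
  searches therefore bottom out at $n = 2$ but rarely return it.
* **Fractional stations.** Budget inversions keep $N_\mathrm{space}$
  fractional (smooth cost curves); rounding up to whole stations is an
  explicit reporting option (`continuous = FALSE`).

## The synthetic world

No public dataset accompanies this kind of pilot survey, so the package
ships a generator (`trend_spec()`, `generate_dataset()`) whose defaults
(`default_world()`) emulate a half-year — 24 roughly weekly occasions from
day 155 to day 338 — at 21 stations of a heterogeneous temperate estuary:
salinity rising slowly, temperature peaking near day 220 and then falling,
oxygen saturation declining, CDOM pulsing between days 218 and 247,
chlorophyll fluctuating irregularly, and PAR decaying with a mean
attenuation of 0.77 m⁻¹. Between-station spreads are configured at the
CV% levels such an area shows for time-integrated means (0.55–12.36%),
with within-station occasion noise an order of magnitude larger
(4–30%), AR(1) autocorrelation ρ = 0.3, and a multiplicative noise model
so configured CVs are scale-free and values stay positive.

One generator decision deserves emphasis: the occasion noise is
*integral-preserving*. The component of each station's noise sequence that
would shift its time-weighted seasonal mean is projected out, so the
realized integrated mean equals the recorded ground truth
`trend_mean * (1 + e_s)` exactly, where `e_s` is the station effect. This
makes ground truth bit-exact and makes "does the pipeline recover the
configured between-station CV?" a well-posed question: the estimated CV is
then an ordinary sample CV of 21 draws, unbiased to within its own
sampling error (about ±1 percentage point at CV 6%). Without the
projection, residual occasion noise (≈ noise_cv/√24, inflated by the
autocorrelation) would alias into the between-station CV and the
generator's reported truth would not be the truth of its own data.

What passing tests on this world do **not** show about real data: real
stations are spatially correlated, real noise is not exactly
multiplicative or AR(1), real casts have measurement error in depth, and
real integrals are *not* noise-free — in the field the between-station CV
genuinely contains a residual temporal component. The generator
demonstrates the machinery and the pooling mechanism, not field CV levels.

## Numerical notes

* Extinction fitting requires ≥ 3 strictly positive irradiance values;
  below-detection points are excluded only via an explicit `floor`
  argument, never silently.
* `min_n_for_power()` is an exact linear search from n = 2; power is
  strictly increasing in n so the first hit is minimal. The search always
  terminates because power → 1 as n → ∞ for d > 0.
* Degenerate inputs are defined, not accidental: a constant dataset yields
  CV 0, one-station designs, a 100% standardized mean for every schedule,
  and an NA Shapiro–Wilk entry (the test is undefined at zero variance).
* Problem sizes used in the validation suite — 21 stations × 24 occasions,
  500-replicate recovery runs, 10,000-replicate empirical power checks —
  were chosen as the smallest sizes at which the Monte-Carlo tolerances
  (±1 percentage point on CV recovery, ±0.02 on rejection rates) are
  comfortably diagnostic.

## Worked example

```{r design}
cvs <- default_cv_set()
cvs

design_table(cvs, target_ci = 5)

budget_for_portfolio(cost_model(), cvs, target_ci = 20)
```

And the full pipeline on synthetic observations:

```{r pipeline}
sim <- generate_dataset(default_world(), n_stations = 21, seed = 42)
report <- run_pipeline(run_config(), sim$observations)
report$summary[, c("variable", "area_mean", "cv_percent", "shapiro_p")]
report$min_frequency
```

## Limitations

The cost model is linear and single-objective (the worst variable sets the
budget); stratified or unequal allocation across stations, non-uniform
within-season schedules (e.g. upweighting March–September), autocorrelation
modelling, and gap-filling beyond midpoint weighting are out of scope. The
t-based calculus assumes the integrated station means are approximately
normal and that CV% is stable between the pilot year and the years being
compared; `normality_check()` tests the first assumption, nothing tests the
second.
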