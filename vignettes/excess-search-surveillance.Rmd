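---
title: "Detecting excess weekly search volume with a seasonal OLS baseline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting excess weekly search volume with a seasonal OLS baseline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(searchexcess)
library(dplyr)
```

## The surveillance problem

Traditional measures of household violence — reports to child-protective
services, police calls — depend on contact with mandated reporters, and that
contact is exactly what a major disruption (a pandemic, a recession)
curtails. Relative search volume is an alternative signal: the probability
that a sampled web search matches a curated set of query terms, scaled by
ten million, reported weekly. The question the pipeline answers is narrow
and operational: *in a target year, which weeks show more searching than the
prepandemic seasonal pattern predicts, and do those weeks cluster in time?*

The package takes weekly series in, fits a seasonal baseline on a training
window, and flags target weeks that escape an out-of-sample prediction
interval. Everything is data-frame-in, tibble-out, so the stages chain with
the pipe.

## Model and assumptions

For training weeks \(t = 1,\dots,n\) with aggregated volume \(y_t\):

\[ y_t = \beta_0 + \beta_1\,d_t + f(w_t) + \varepsilon_t,
   \qquad \varepsilon_t \sim \mathcal N(0, \sigma^2)\ \text{i.i.d.} \]

* \(d_t\): calendar date in fractional years since a configurable origin
  (default: the first training week). The unit choice only rescales
  \(\beta_1\); fitted values are invariant, which the tests verify.
* \(f\): a restricted cubic spline of the continuous week-of-year
  coordinate \(w_t \in [1, 54)\), with knots at the 10th, 50th and 90th
  percentiles of the training \(w\) values. With 3 knots the spline
  contributes \(k-1=2\) columns (Harrell's truncated-power basis,
  normalized by \((t_k-t_1)^2\)); the function is linear beyond the
  boundary knots with continuous first and second derivatives. Any
  rank-equivalent natural-spline basis gives identical fitted values — a
  property tested against `splines::ns`, not assumed.
* Estimation is ordinary least squares (`stats::lm()` behind
  `fit_baseline()`); no autocorrelation correction is applied. Residual
  diagnostics (`residual_diagnostics()`) flag skewness and lag-1
  autocorrelation but never alter the estimator: the baseline is
  deliberately the plain-OLS one.

For a target week with design row \(x_0\) built with the *same* knots and
origin, the level-\(L\) prediction interval is

\[ x_0^\top\hat\beta \;\pm\; t_{1-(1-L)/2,\,n-p}\; s\,
   \sqrt{1 + x_0^\top (X^\top X)^{-1} x_0}. \]

Two details are contractual. First, it is a prediction interval — the
leading 1 under the root — because the target of inference is an individual
future weekly observation; by design a fraction \(1-L\) of null weeks falls
outside. Second, the quantile is Student-t with \(n-p\) degrees of freedom,
not normal: with 157 training weeks the difference is under 1%, but the
coverage contract is then exact under the model.

### Week grid and week-of-year coordinate

Weeks start on Sunday (the provider's convention); the grid holds every
Sunday inside the window. For 2017-01-01 to 2019-12-31 this gives exactly
157 training weeks (2017-01-01 was itself a Sunday) and 52 full weeks for
2020 — matching the week counts of the motivating study design. The
week-of-year coordinate is continuous, \((\text{day-of-year}-1)/7 + 1\), so
the same calendar season lands on slightly different coordinates across
years, as in the raw data. The spline is *not* periodic: the Dec→Jan
boundary is a genuine discontinuity of the seasonal curve, kept because the
reference analysis has it too.

### Knot placement

Percentile knots use the linear-interpolation quantile definition (R type
7). The tests pin this down with an independent sort-and-interpolate
oracle: weeks 1…52 observed three times each put the knots at exactly
(6, 26.5, 47). Reading "interior knots at the 10th/50th/90th percentiles"
as *exactly three knots total* is the minimal interpretation; no
boundary-knot rule beyond the three stated locations is recoverable, and
with the leverage-dominated prediction bands the choice is second-order.

## The synthetic generator

`generate_series()` emulates what the search API returns, with mean
structure

\[ \mu(t) = m + b\,\text{years}(t)
   + A\cos\!\big(2\pi\,(w_t - w_{\text{peak}})/52\big)
   \;+\; \text{excess}(t), \]

one week-level Gaussian deviation (SD \(\sigma_w\)) shared by all
replicates of the week, and independent replicate deviations (SD
\(\sigma_r\)) for each of \(n_r\) replicate extractions. Aggregated weekly
values therefore have variance \(\sigma_w^2 + \sigma_r^2/n_r\), a
decomposition the tests verify by Monte Carlo. Week-level noise is drawn
before replicate noise under one seed, so adding replicates never perturbs
the week-level draws. Values below the suppression threshold are emitted as
missing; the threshold defaults to 0 (suppression effectively off) because
the provider's lower bound is unspecified, and negative draws are always
suppressed so emitted volumes are nonnegative.

Defaults are calibrated once to the published scale of the child-abuse
outcome and then left alone:

| parameter | default | rationale |
|---|---|---|
| `baseline_mean` | 85.0 | 2017 yearly mean of the child-abuse series |
| `trend_slope` | −0.6 /yr | slight year-to-year decline (85.0 → 83.8 over two years) |
| `seasonal_amplitude` | 4.5 | seasonal share of variance ≈ 15%, the reported fit quality for that outcome |
| `seasonal_peak_week` | 23 (early June) | "highest in June" |
| `week_noise_sd` | 7 | total weekly SD ≈ 7.2, inside the published 6.3–9.4 yearly SD range |
| `replicate_noise_sd` | 2 | small relative to week noise, as the mean–median agreement implies |
| `n_replicates` | 10 | the provider extraction count |

`preset_params()` adds analogous presets for the two intimate-partner-
violence outcomes (December peak at a lower level; nearly flat seasonality
with weak signal). A single cosine cannot reproduce *both* reported
extremes of the child-abuse series (June peak, January trough — not
antipodal weeks); the generator keeps the cosine, placing the trough 26
weeks after the peak, rather than inventing a richer seasonal shape the
source never describes.

`excess_spec()` injects departures from a start date: a step of constant
magnitude, a linear ramp rising to the magnitude over its duration, or an
exponential decay with the duration as e-folding time. Negative magnitudes
emulate deficits. The default start, 2020-08-30, mirrors the timing
structure of the motivating findings (about four weeks after the
unemployment-supplement expiry, 2020-07-31).

### What the generator does not emulate

Real search series have autocorrelated week-to-week shocks, media-driven
spikes, non-Gaussian tails, and a seasonal shape richer than one harmonic.
Passing tests on generator data therefore demonstrate that the *pipeline*
is correct and calibrated under its own assumptions — not that real search
volumes satisfy those assumptions. The residual diagnostics exist precisely
to check the latter on real data.

## Exceedance, notability, runs

`classify_weeks()` flags each target week `above`/`below` by *strict*
comparison with the band; a tie counts as `within` (conservative, and the
source is silent on ties). Missing weeks propagate and break runs.

At level 0.95, \(0.05 \times 52 = 2.6\) outside-weeks are expected. The
summary (`exceedance_vs_null()`) calls a result **notable** when the
outside count strictly exceeds \(\lceil 2.6 \rceil = 3\), and **marginal**
when it exceeds 2.6 but not the ceiling — three outside-weeks of 52 is more
than expected yet indistinguishable from what prepandemic years show. An
exact binomial tail probability accompanies the counts as descriptive
context only; it assumes independent weeks, which serially correlated
residuals would violate, so it is never a gate. Serial above-runs
(`detect_runs()`, maximal and disjoint) carry the real evidential weight:
under the null the longest run in 52 weeks averages well under one week,
so multi-week runs are the signature of a genuine excess.

Null calibration is not hypothetical: the acceptance suite simulates 500
replicates of the full design and recovers a mean outside-fraction of 5%
(±1 percentage point) and nominal coverage at levels 0.80/0.90/0.95.

## Numerical and design choices

* **Quantiles** — type 7, so knot oracles are exact.
* **\((X^\top X)^{-1}\)** — computed by Cholesky on the 4-column design and
  stored in the fit, making prediction independent of the training data and
  the serialized model (`write_baseline_json()`) self-contained.
* **Degenerate fits** — noise-free series give residual variance 0; the
  band collapses to the point prediction and diagnostics report
  `degenerate` rather than erroring.
* **Rank checks** — collinear spline columns (e.g. knots outside the data
  range) abort the fit with a clear message rather than silently dropping
  terms.
* **Determinism** — every stochastic step flows from one integer seed; the
  pipeline writes byte-identical artifacts for a fixed config, which the
  tests assert literally.
* **Missing weeks** — dropped from fitting (no imputation rule exists in
  the source), carried as `missing` flags in reports.
* **Policy dates** — shelter-in-place onset (2020-03-19), impact payments
  (2020-04-17), unemployment-supplement expiry (2020-07-31) ship as plot
  annotations only and never enter any computation.

### Problem sizes used in validation

The test suite and acceptance script run on the study-sized grid (157 + 52
weeks, 10 replicates): 500 null replicates for calibration and coverage, 60
replicates for detection power, 100 random instances for the OLS oracle,
and a 1000-year flat series for the large-sample half-width limit. On one
CPU the whole suite runs in well under a minute.

## Limitations

The pipeline inherits the method's own caveats. It detects *departures from
an extrapolated seasonal pattern*, not violence; the link between search
volume and incidence is an external assumption. Per-week interval tests
multiply across 52 weeks — the run structure is an informal, not a formal,
multiplicity answer. The linear trend extrapolates one year beyond
training; a curving secular trend would masquerade as excess. And with only
three prepandemic years, the seasonal spline has 2 degrees of freedom —
deliberately stiff, which bounds variance at the cost of residual seasonal
lack-of-fit that inflates the interval width slightly.
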