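# searchexcess

Syndromic surveillance from search data: detect weeks of **excess relative
search volume** against a prepandemic seasonal baseline. The package was
built for infoveillance studies of household-violence proxies — weekly,
national-level Google search volumes for terms that people experiencing or
witnessing child abuse or intimate partner violence might type — but the
machinery applies to any weekly series with smooth within-year seasonality,
a mild secular trend, and replicate sampling noise.

Because such search APIs are key-gated and their raw series cannot be
redistributed, the package ships a calibrated synthetic-data generator that
emulates the provider's output (replicate samples, probability × 10⁷
scaling, value suppression), so the entire analysis chain is testable and
reproducible without any download.

## The model

For prepandemic training weeks (by default the 157 Sunday-start weeks of
2017–2019), the weekly aggregated volume \(y_t\) is modelled by ordinary
least squares as

```
y_t = β₀ + β₁ · date_t + f(week-of-year_t) + ε_t,      ε_t ~ N(0, σ²)
```

where `date` is calendar time in fractional years (the linear secular
trend) and `f` is a restricted cubic spline (natural cubic spline) of the
week of year with knots at the 10th, 50th and 90th percentiles of the
training weeks — linear beyond its boundary knots, 2 seasonal degrees of
freedom with 3 knots.

Each target week (the 52 weeks of 2020 by default) gets a point prediction
\(x_0'\hat\beta\) and a 95% **prediction interval**

```
x₀'β̂ ± t₀.₉₇₅,ₙ₋ₚ · s · √(1 + x₀'(X'X)⁻¹x₀)
```

which bounds an individual future observation, not its mean: under the null
about 5% of target weeks (≈ 2–3 of 52) should fall outside. Weeks strictly
above the upper bound are exceedance weeks; more outside-weeks than the
integer ceiling of the expected count is a *notable* excess, and serially
clustered above-runs are the informal evidence that the signal is not a
multiple-testing artifact.

## Worked example

Simulate a child-abuse-like series with a 20-unit step excess injected on
2020-08-30, fit the baseline on 2017–2019, and classify 2020:

```r
library(searchexcess)
library(dplyr)

params <- preset_params("child_abuse", seed = 11)
series <- generate_series(params, excess_spec("2020-08-30", 20, "step")) |>
  aggregate_replicates()

train  <- filter(series, week_start_date <= as.Date("2019-12-31"))
target <- filter(series, week_start_date >= as.Date("2020-01-01"))

fit <- fit_baseline(train)
fit
#> <search_baseline> OLS seasonal baseline
#>   157 training weeks (2017-01-01 to 2019-12-29), 4 coefficients
#>   adjusted R^2 = 0.123, residual SD = 6.825 on 153 df
#>   knots at week-of-year  6.428571, 27.000000, 47.914286

report <- classify_weeks(target, predict_band(fit, target$week_start_date))
report
#> <excess_report> 52 weeks at level 0.95
#>   above: 15, below: 0, within: 37, missing: 0
#>   outside: 15/52 (28.8%), expected 5.0%
#>   4 above-run(s), longest 5 week(s); first above week 2020-07-12
```

15 of 52 weeks sit above the band against the ~2.6 expected by chance. The
run table separates the one isolated pre-onset singleton (the false alarm a
95% interval permits) from the serial post-onset signal:

```r
report$runs
#>   start_date length
#> 1 2020-07-12      1
#> 2 2020-09-06      5
#> 3 2020-10-18      4
#> 4 2020-11-22      5

glance(report)    # notable = TRUE, p_binomial = 2.3e-08
```

`autoplot(report)` draws the observed points, predicted curve, interval
ribbon and dashed policy-date markers (shelter-in-place onset, impact
payments, unemployment-supplement expiry). `run_pipeline(pipeline_config(...),
output_dir = "out")` performs the whole chain config-driven and writes
`model.json`, `band.csv`, `flags.csv` and `report.json`;
`inst/scripts/searchexcess.R` is a thin command-line wrapper around it.

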