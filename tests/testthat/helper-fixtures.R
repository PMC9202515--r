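# Shared fixtures: all synthetic, built in code at test time.

# Deterministic generator: no noise, no season, no trend.
flat_params <- function(mean = 85, n_replicates = 3, ...) {
  generator_params(
    baseline_mean = mean, trend_slope = 0, seasonal_amplitude = 0,
    week_noise_sd = 0, replicate_noise_sd = 0, n_replicates = n_replicates,
    ...
  )
}

# A standard aggregated training series (2017-2019) and target year (2020).
make_split <- function(seed, params = generator_params(seed = seed),
                       excess = NULL) {
  params$seed <- as.integer(seed)
  s <- aggregate_replicates(generate_series(params, excess))
  list(
    train = s[s$week_start_date <= as.Date("2019-12-31"), ],
    target = s[s$week_start_date >= as.Date("2020-01-01"), ]
  )
}

# Hand-rolled linear-interpolation quantile, independent of stats::quantile.
interp_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Build an excess_report with a prescribed number of above/below weeks by
# shifting observations relative to a flat band.
report_with_counts <- function(n_weeks, n_above, n_below = 0, level = 0.95) {
  dates <- week_grid("2020-01-01", "2020-12-31")[seq_len(n_weeks)]
  band <- tibble::tibble(
    week_start_date = dates, point = 50, lower = 40, upper = 60,
    level = level
  )
  class(band) <- c("search_band", class(band))
  value <- rep(50, n_weeks)
  if (n_above > 0) value[seq_len(n_above)] <- 61
  if (n_below > 0) value[n_weeks - seq_len(n_below) + 1] <- 39
  obs <- tibble::tibble(
    week_start_date = dates, week_of_year = week_of_year(dates),
    replicates = rep(list(numeric()), n_weeks), value = value
  )
  classify_weeks(obs, band)
}
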