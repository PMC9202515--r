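test_that("week grid follows the Sunday-start convention and study counts", {
  tr <- week_grid("2017-01-01", "2019-12-31")
  tg <- week_grid("2020-01-01", "2020-12-31")
  expect_length(tr, 157)
  expect_length(tg, 52)
  expect_true(all(format(c(tr, tg), "%u") == "7"))
  expect_true(all(diff(tr) == 7))
  expect_identical(tg[1], as.Date("2020-01-05"))
})

test_that("noise-free generator reproduces the closed-form mean curve exactly", {
  # fully degenerate case: every replicate of every week equals the mean
  s <- generate_series(flat_params(mean = 85))
  expect_true(all(vapply(s$replicates, function(v) all(v == 85), logical(1))))

  # seasonal + trend, still noise-free: exact cosine-plus-trend curve
  p <- generator_params(
    baseline_mean = 85, trend_slope = -0.6, seasonal_amplitude = 4.5,
    seasonal_peak_week = 23, week_noise_sd = 0, replicate_noise_sd = 0
  )
  s <- aggregate_replicates(generate_series(p))
  yrs <- as.numeric(s$week_start_date - p$start_date) / 365.25
  expected <- 85 - 0.6 * yrs + 4.5 * cos(2 * pi * (s$week_of_year - 23) / 52)
  expect_equal(s$value, expected, tolerance = 1e-12)

  # peak lands in June-dated weeks, trough about half a cycle away
  one_year <- s[format(s$week_start_date, "%Y") == "2018", ]
  peak_month <- format(one_year$week_start_date[which.max(one_year$value)], "%m")
  trough <- one_year$week_of_year[which.min(one_year$value)]
  expect_identical(peak_month, "06")
  expect_lt(abs(abs(trough - 23) - 26), 2)
})

test_that("generation is deterministic in the seed and stable in replicate count", {
  p <- generator_params(seed = 11)
  s1 <- generate_series(p)
  s2 <- generate_series(p)
  expect_identical(s1, s2)
  p2 <- p
  p2$seed <- 12L
  expect_false(identical(generate_series(p2)$replicates, s1$replicates))

  # week-level noise is drawn before replicate noise: growing n_replicates
  # leaves existing replicates' values untouched
  p5 <- generator_params(seed = 11, n_replicates = 5)
  p8 <- generator_params(seed = 11, n_replicates = 8)
  r5 <- generate_series(p5)$replicates
  r8 <- generate_series(p8)$replicates
  expect_equal(
    lapply(r8, function(v) v[1:5]), r5,
    tolerance = 1e-15
  )
})

test_that("aggregated weekly variance decomposes as week + replicate/n", {
  # 200-week window, no signal: var(aggregate) = w^2 + r^2 / n_rep
  p <- generator_params(
    baseline_mean = 100, trend_slope = 0, seasonal_amplitude = 0,
    week_noise_sd = 5, replicate_noise_sd = 2, n_replicates = 10,
    start_date = "2017-01-01", end_date = "2020-10-25", seed = 301
  )
  vals <- unlist(lapply(1:8, function(i) {
    p$seed <- 300L + i
    aggregate_replicates(generate_series(p))$value
  }))
  expect_length(vals, 8 * 200)
  target_sd <- sqrt(5^2 + 2^2 / 10)
  expect_equal(sd(vals), target_sd, tolerance = 0.05)
})

test_that("injected excess shapes act on the mean curve as specified", {
  base <- flat_params(mean = 85, n_replicates = 1)
  start <- as.Date("2020-08-30")
  s0 <- aggregate_replicates(generate_series(base))
  post <- s0$week_start_date >= start

  step <- aggregate_replicates(
    generate_series(base, excess_spec(start, magnitude = 7, shape = "step"))
  )
  expect_equal(step$value[post], s0$value[post] + 7, tolerance = 1e-12)
  expect_equal(step$value[!post], s0$value[!post], tolerance = 1e-12)

  ramp <- aggregate_replicates(generate_series(
    base, excess_spec(start, 10, shape = "linear-ramp", duration_weeks = 5)
  ))
  k <- as.numeric(ramp$week_start_date - start) / 7
  active <- k >= 0 & k < 5
  expect_equal(ramp$value[active] - s0$value[active], 10 * (k[active] + 1) / 5,
    tolerance = 1e-12
  )
  expect_equal(ramp$value[!active], s0$value[!active], tolerance = 1e-12)

  decay <- aggregate_replicates(generate_series(
    base, excess_spec(start, 10, shape = "exponential-decay", duration_weeks = 4)
  ))
  act2 <- k >= 0 & k < 4
  expect_equal(decay$value[act2] - s0$value[act2], 10 * exp(-k[act2] / 4),
    tolerance = 1e-12
  )

  # negative magnitude emulates a deficit
  deficit <- aggregate_replicates(
    generate_series(base, excess_spec(start, -5, shape = "step"))
  )
  expect_equal(deficit$value[post], s0$value[post] - 5, tolerance = 1e-12)
})

test_that("parameter and excess validation rejects bad input", {
  expect_error(generator_params(week_noise_sd = -1), "nonnegative")
  expect_error(generator_params(baseline_mean = Inf), "non-finite")
  expect_error(generator_params(seasonal_peak_week = 60), "1, 52")
  expect_error(generator_params(n_replicates = 0), "positive integer")
  expect_error(
    generator_params(start_date = "2020-01-01", end_date = "2019-01-01"),
    "precede"
  )
  expect_error(
    generate_series(
      generator_params(),
      excess_spec("2025-01-01", 5, shape = "step")
    ),
    "outside the series window"
  )
  expect_error(
    excess_spec("2020-01-01", 5, shape = "linear-ramp", duration_weeks = Inf),
    "finite"
  )
  expect_error(aggregate_replicates(generate_series(flat_params()), "mode"))
})

test_that("suppression turns small values into missing, never negative values", {
  p <- generator_params(
    baseline_mean = 3, trend_slope = 0, seasonal_amplitude = 0,
    week_noise_sd = 3, replicate_noise_sd = 1, suppression_threshold = 2,
    seed = 5
  )
  s <- generate_series(p)
  vals <- unlist(s$replicates)
  expect_true(any(is.na(vals)))
  expect_true(all(vals[!is.na(vals)] >= 2))
  agg <- aggregate_replicates(s)
  # weeks with zero usable replicates stay missing
  if (any(vapply(s$replicates, function(v) all(is.na(v)), logical(1)))) {
    expect_true(any(is.na(agg$value)))
  }
})

test_that("replicate aggregation matches its definition and mean tracks median", {
  s <- tibble::tibble(
    week_start_date = week_grid("2020-01-05", "2020-01-18"),
    week_of_year = 1:2,
    replicates = list(c(10, 20, 30), c(10, 20, 90)),
    value = NA_real_
  )
  expect_equal(aggregate_replicates(s, "mean")$value, c(20, 40))
  expect_equal(aggregate_replicates(s, "median")$value, c(20, 20))
  # missing replicates are dropped before aggregating
  s$replicates[[1]] <- c(10, NA, 30)
  expect_equal(aggregate_replicates(s, "mean")$value[1], 20)

  # with 10 replicates of Gaussian sampling noise, mean and median of a week
  # differ by much less than the replicate SD on average
  p <- generator_params(
    week_noise_sd = 5, replicate_noise_sd = 2, n_replicates = 10,
    start_date = "2005-01-01", end_date = "2024-12-31", seed = 77
  )
  g <- generate_series(p)
  expect_gte(nrow(g), 1000)
  d <- abs(aggregate_replicates(g, "mean")$value -
    aggregate_replicates(g, "median")$value)
  expect_lt(mean(d), 2)
})
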