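#' Parameters of the synthetic weekly search-volume generator
#'
#' The generator emulates weekly relative search volumes as returned by a
#' sampled search API: probabilities scaled by 10 million, observed through
#' several replicate extractions per week. Each week's mean follows a linear
#' secular trend plus a single-cosine seasonal cycle; one Gaussian week-level
#' deviation is shared by all replicates of that week, and each replicate
#' adds its own independent Gaussian deviation. Values below
#' `suppression_threshold` are emitted as missing, mirroring the provider's
#' suppression of small volumes.
#'
#' Defaults are calibrated to the child-abuse search series: a 2017 mean of
#' 85.0 volume units with a slight year-to-year decline, a June seasonal peak
#' (week 23), and noise scales chosen so the seasonal signal accounts for
#' roughly 15% of weekly variance at a total SD near the observed 8--9 units.
#'
#' @param baseline_mean Mean volume (probability x 1e7) at `start_date`.
#' @param trend_slope Volume units per year; negative for a declining trend.
#' @param seasonal_amplitude Cosine amplitude, volume units.
#' @param seasonal_peak_week Week of year (in `[1, 52]`) at which the
#'   seasonal cosine peaks; the trough lies 26 weeks away.
#' @param week_noise_sd SD of the week-level deviation shared by replicates.
#' @param replicate_noise_sd SD of the per-replicate sampling deviation.
#' @param n_replicates Replicate extractions per week (provider default 10).
#' @param start_date,end_date Window bounds; weeks are Sundays inside it.
#' @param suppression_threshold Values strictly below this are missing;
#'   0 disables suppression of positive values (negative draws still
#'   suppress, keeping all emitted values nonnegative).
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @return A list of class `generator_params`.
#' @seealso [generate_series()], [preset_params()]
#' @export
generator_params <- function(baseline_mean = 85,
                             trend_slope = -0.6,
                             seasonal_amplitude = 4.5,
                             seasonal_peak_week = 23,
                             week_noise_sd = 7,
                             replicate_noise_sd = 2,
                             n_replicates = 10,
                             start_date = "2017-01-01",
                             end_date = "2020-12-31",
                             suppression_threshold = 0,
                             seed = NULL) {
  start_date <- as_iso_date(start_date, "start_date")
  end_date <- as_iso_date(end_date, "end_date")
  num <- c(
    baseline_mean = baseline_mean, trend_slope = trend_slope,
    seasonal_amplitude = seasonal_amplitude,
    seasonal_peak_week = seasonal_peak_week,
    week_noise_sd = week_noise_sd, replicate_noise_sd = replicate_noise_sd,
    n_replicates = n_replicates,
    suppression_threshold = suppression_threshold
  )
  if (any(!is.finite(num))) {
    abort(sprintf(
      "non-finite generator parameter(s): %s",
      paste(names(num)[!is.finite(num)], collapse = ", ")
    ))
  }
  if (week_noise_sd < 0 || replicate_noise_sd < 0) {
    abort("noise SDs must be nonnegative.")
  }
  if (n_replicates < 1 || n_replicates != round(n_replicates)) {
    abort("`n_replicates` must be a positive integer.")
  }
  if (seasonal_peak_week < 1 || seasonal_peak_week > 52) {
    abort("`seasonal_peak_week` must lie in [1, 52].")
  }
  if (start_date >= end_date) {
    abort("`start_date` must precede `end_date`.")
  }
  structure(
    list(
      baseline_mean = baseline_mean, trend_slope = trend_slope,
      seasonal_amplitude = seasonal_amplitude,
      seasonal_peak_week = seasonal_peak_week,
      week_noise_sd = week_noise_sd,
      replicate_noise_sd = replicate_noise_sd,
      n_replicates = as.integer(n_replicates),
      start_date = start_date, end_date = end_date,
      suppression_threshold = suppression_threshold,
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    class = "generator_params"
  )
}

#' Calibrated generator presets for the three violence-related outcomes
#'
#' Each preset matches the published yearly means/SDs and the stated
#' seasonal peak month of one search outcome: child-abuse searches peak in
#' June and decline slightly year to year; child-witnessed intimate partner
#' violence (IPV) searches peak in December at a lower overall level; IPV
#' searches are nearly flat seasonally with a weak seasonal signal.
#'
#' @param outcome One of `"child_abuse"`, `"child_witnessed_ipv"`, `"ipv"`.
#' @param ... Overrides passed on to [generator_params()].
#' @return A `generator_params` object.
#' @export
preset_params <- function(outcome = c("child_abuse", "child_witnessed_ipv", "ipv"),
                          ...) {
  outcome <- match.arg(outcome)
  base <- switch(outcome,
    child_abuse = list(
      baseline_mean = 85, trend_slope = -0.6, seasonal_amplitude = 4.5,
      seasonal_peak_week = 23, week_noise_sd = 7
    ),
    child_witnessed_ipv = list(
      baseline_mean = 60, trend_slope = -0.85, seasonal_amplitude = 3.2,
      seasonal_peak_week = 50, week_noise_sd = 5.6
    ),
    ipv = list(
      baseline_mean = 81, trend_slope = 0, seasonal_amplitude = 1.2,
      seasonal_peak_week = 26, week_noise_sd = 6.4
    )
  )
  do.call(generator_params, utils::modifyList(base, list(...)))
}

#' Specification of an injected excess (or deficit)
#'
#' Describes a departure from the baseline mean curve beginning at a
#' calendar date, used to emulate pandemic-era excess searches and to power
#' detection studies. Shapes: `"step"` adds `magnitude` for every active
#' week; `"linear-ramp"` rises linearly to `magnitude` over
#' `duration_weeks`; `"exponential-decay"` starts at `magnitude` and decays
#' with e-folding time `duration_weeks`.
#'
#' @param start_date First affected week (calendar date; the first grid week
#'   on or after it is the first active week).
#' @param magnitude Volume units; negative values emulate deficits.
#' @param shape One of `"step"`, `"linear-ramp"`, `"exponential-decay"`.
#' @param duration_weeks Number of active weeks, or `Inf` for open-ended
#'   (allowed for `"step"` only; the two graded shapes need a finite scale).
#' @return A list of class `excess_spec`.
#' @export
excess_spec <- function(start_date = "2020-08-30",
                        magnitude = 20,
                        shape = c("step", "linear-ramp", "exponential-decay"),
                        duration_weeks = Inf) {
  shape <- match.arg(shape)
  start_date <- as_iso_date(start_date, "start_date")
  if (!is.finite(magnitude)) abort("`magnitude` must be finite.")
  if (duration_weeks <= 0) abort("`duration_weeks` must be positive.")
  if (!is.finite(duration_weeks) && shape != "step") {
    abort(sprintf("shape '%s' requires a finite `duration_weeks`.", shape))
  }
  structure(
    list(
      start_date = start_date, magnitude = magnitude, shape = shape,
      duration_weeks = duration_weeks
    ),
    class = "excess_spec"
  )
}

# Mean curve: trend in fractional years since the series start plus a
# single-cosine seasonal cycle with period 52 weeks.
mean_curve <- function(params, dates) {
  yrs <- as.numeric(dates - params$start_date) / 365.25
  params$baseline_mean + params$trend_slope * yrs +
    params$seasonal_amplitude *
      cos(2 * pi * (week_of_year(dates) - params$seasonal_peak_week) / 52)
}

excess_curve <- function(excess, dates) {
  if (is.null(excess)) {
    return(numeric(length(dates)))
  }
  k <- as.numeric(dates - excess$start_date) / 7 # weeks since onset
  active <- k >= 0 & k < excess$duration_weeks
  out <- numeric(length(dates))
  d <- excess$duration_weeks
  out[active] <- switch(excess$shape,
    "step" = excess$magnitude,
    "linear-ramp" = excess$magnitude * (k[active] + 1) / d,
    "exponential-decay" = excess$magnitude * exp(-k[active] / d)
  )
  out
}

#' Generate a synthetic weekly search-volume series
#'
#' Draws a weekly series on the Sunday grid of `params`: mean curve plus one
#' shared week-level Gaussian deviation and independent per-replicate
#' deviations. All week-level noise is drawn before any replicate noise, so
#' increasing `n_replicates` leaves the week-level draws (and every existing
#' replicate's draw) unchanged under the same seed. Values below the
#' suppression threshold become missing.
#'
#' @param params A [generator_params()] object.
#' @param excess Optional [excess_spec()]; its start date must fall inside
#'   the series window.
#' @return A `search_series` tibble with one row per week: `week_start_date`,
#'   `week_of_year`, `replicates` (list column of replicate draws), and
#'   `value` (aggregated volume, `NA` until [aggregate_replicates()] runs).
#' @examples
#' params <- generator_params(seed = 42)
#' series <- generate_series(params) |> aggregate_replicates()
#' head(series)
#' @export
generate_series <- function(params, excess = NULL) {
  stopifnot(inherits(params, "generator_params"))
  if (!is.null(excess)) {
    stopifnot(inherits(excess, "excess_spec"))
    if (excess$start_date < params$start_date ||
      excess$start_date > params$end_date) {
      abort("excess start date falls outside the series window.")
    }
  }
  dates <- week_grid(params$start_date, params$end_date)
  n <- length(dates)
  mu <- mean_curve(params, dates) + excess_curve(excess, dates)

  if (!is.null(params$seed)) set.seed(params$seed)
  week_dev <- rnorm(n, 0, params$week_noise_sd)
  rep_dev <- matrix(rnorm(n * params$n_replicates, 0, params$replicate_noise_sd),
    nrow = n
  )
  values <- mu + week_dev + rep_dev
  values[values < params$suppression_threshold | values < 0] <- NA_real_

  new_search_series(tibble::tibble(
    week_start_date = dates,
    week_of_year = week_of_year(dates),
    replicates = lapply(seq_len(n), function(i) unname(values[i, ])),
    value = NA_real_
  ))
}

new_search_series <- function(df) {
  class(df) <- c("search_series", class(df))
  df
}

#' Aggregate replicate extractions into one weekly value
#'
#' The provider returns several replicate estimates per week; the analysis
#' uses their mean (the published choice — mean and median differ little).
#' Missing replicates are dropped; weeks with no usable replicate keep a
#' missing aggregate.
#'
#' @param series A `search_series` tibble with a `replicates` list column.
#' @param method `"mean"` (default) or `"median"`.
#' @return The series with `value` populated; replicates untouched.
#' @export
aggregate_replicates <- function(series, method = c("mean", "median")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(series), "replicates" %in% names(series))
  agg <- if (method == "mean") mean else median
  series$value <- purrr::map_dbl(series$replicates, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else agg(v)
  })
  new_search_series(series)
}
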