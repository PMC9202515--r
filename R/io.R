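#' Read and write weekly search-volume series as CSV
#'
#' Two on-disk schemas are supported. Long (replicate) format has columns
#' `week_start_date` (ISO-8601), `replicate_id`, `value` — one row per
#' replicate extraction; aggregated format has `week_start_date`, `value` —
#' one row per week, aggregation already done. `read_series_csv()` detects
#' the schema from the header. A write-then-read round trip is the identity
#' on dates and values.
#'
#' @param path File path.
#' @return `read_series_csv()`: a `search_series` tibble. For long files
#'   `value` is left missing until [aggregate_replicates()] runs; for
#'   aggregated files `replicates` is an empty list column.
#' @export
read_series_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  long <- all(c("week_start_date", "replicate_id", "value") %in% names(raw))
  aggregated <- !long && all(c("week_start_date", "value") %in% names(raw))
  if (!long && !aggregated) {
    abort(paste0(
      "unrecognized series schema in '", path,
      "': need columns week_start_date, replicate_id, value (long) ",
      "or week_start_date, value (aggregated)."
    ))
  }
  dates <- as.Date(raw$week_start_date, format = "%Y-%m-%d")
  if (any(is.na(dates) & !is.na(raw$week_start_date))) {
    bad <- which(is.na(dates) & !is.na(raw$week_start_date))[1]
    abort(sprintf(
      "non-ISO date '%s' at data row %d of '%s'.",
      raw$week_start_date[bad], bad, path
    ))
  }
  if (long) {
    dup <- duplicated(raw[c("week_start_date", "replicate_id")])
    if (any(dup)) {
      abort(sprintf(
        "duplicated week/replicate pair (%s, %s) in '%s'.",
        raw$week_start_date[dup][1], raw$replicate_id[dup][1], path
      ))
    }
    weeks <- sort(unique(dates))
    reps <- split(raw$value, match(dates, weeks))
    series <- tibble::tibble(
      week_start_date = weeks,
      week_of_year = week_of_year(weeks),
      replicates = lapply(as.character(seq_along(weeks)), function(i) {
        unname(reps[[i]])
      }),
      value = NA_real_
    )
  } else {
    if (anyDuplicated(dates)) {
      abort(sprintf(
        "duplicated week %s in '%s'.",
        format(dates[duplicated(dates)][1]), path
      ))
    }
    ord <- order(dates)
    series <- tibble::tibble(
      week_start_date = dates[ord],
      week_of_year = week_of_year(dates[ord]),
      replicates = rep(list(numeric()), length(dates)),
      value = as.numeric(raw$value)[ord]
    )
  }
  check_week_spacing(series$week_start_date, path)
  new_search_series(series)
}

check_week_spacing <- function(dates, path) {
  if (length(dates) > 1 && any(diff(as.integer(dates)) != 7)) {
    warn(sprintf("weeks in '%s' are not evenly spaced 7 days apart.", path))
  }
  invisible(dates)
}

#' @rdname read_series_csv
#' @param series A `search_series`.
#' @param format `"long"` writes one row per replicate; `"aggregated"`
#'   writes one row per week using the `value` column.
#' @export
write_series_csv <- function(series, path, format = c("long", "aggregated")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(series))
  if (format == "long") {
    out <- tidyr::unnest_longer(
      tibble::tibble(
        week_start_date = format(series$week_start_date),
        value = series$replicates
      ),
      "value",
      indices_to = "replicate_id"
    )[c("week_start_date", "replicate_id", "value")]
  } else {
    out <- data.frame(
      week_start_date = format(series$week_start_date),
      value = series$value
    )
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fitted baseline to JSON and back
#'
#' The JSON model file carries everything [predict_band()] needs —
#' coefficients (with the trend unit recorded as fractional years), knots,
#' date origin, residual variance and degrees of freedom, and
#' \eqn{(X^\top X)^{-1}} — so a band can be reproduced without refitting or
#' access to the training data.
#'
#' @param fit A `search_baseline`.
#' @param path File path for the JSON model file.
#' @export
write_baseline_json <- function(fit, path) {
  stopifnot(inherits(fit, "search_baseline"))
  payload <- list(
    model = "seasonal-ols-baseline",
    coefficient_names = names(fit$coefficients),
    coefficients = unname(fit$coefficients),
    date_unit = "years since date_origin (365.25-day years)",
    date_origin = format(fit$date_origin),
    knots = fit$knots$knots,
    knot_source_percentiles = fit$knots$source_percentiles,
    residual_variance = fit$residual_variance,
    residual_df = fit$residual_df,
    xtx_inverse = unname(fit$xtx_inverse),
    adjusted_r2 = fit$adjusted_r2,
    training_window = format(fit$training_window),
    n_train = fit$n_train
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_baseline_json
#' @return `read_baseline_json()`: a `search_baseline` (without the
#'   training residuals or the underlying `lm` object).
#' @export
read_baseline_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  xtxi <- matrix(unlist(j$xtx_inverse),
    nrow = length(j$coefficients), byrow = TRUE
  )
  dimnames(xtxi) <- list(j$coefficient_names, j$coefficient_names)
  structure(
    list(
      coefficients = setNames(j$coefficients, j$coefficient_names),
      residual_variance = j$residual_variance,
      residual_df = j$residual_df,
      xtx_inverse = xtxi,
      knots = new_knot_set(j$knots, j$knot_source_percentiles),
      date_origin = as.Date(j$date_origin),
      adjusted_r2 = j$adjusted_r2,
      training_window = as.Date(j$training_window),
      n_train = j$n_train,
      residuals = NULL,
      lm = NULL
    ),
    class = "search_baseline"
  )
}

#' Write a prediction band or per-week flags as CSV
#'
#' @param band A `search_band`.
#' @param path File path.
#' @export
write_band_csv <- function(band, path) {
  out <- data.frame(
    week_start_date = format(band$week_start_date),
    point = band$point, lower = band$lower, upper = band$upper,
    level = band$level
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_band_csv
#' @export
read_band_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::tibble(
    week_start_date = as.Date(raw$week_start_date),
    point = raw$point, lower = raw$lower, upper = raw$upper,
    level = raw$level
  )
  class(out) <- c("search_band", class(out))
  out
}

#' @rdname write_band_csv
#' @param report An `excess_report`.
#' @export
write_flags_csv <- function(report, path) {
  w <- report$weeks
  out <- data.frame(
    week_start_date = format(w$week_start_date),
    observed = w$observed, point = w$point,
    lower = w$lower, upper = w$upper, flag = w$flag
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an excess report as JSON
#'
#' Serializes per-week flags, totals, runs, the first-excess date, and the
#' null-comparison summary in one machine-readable file.
#'
#' @param report An `excess_report`.
#' @param path File path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "excess_report"))
  summary_row <- as.list(exceedance_vs_null(report))
  payload <- list(
    level = report$level,
    n_weeks = report$n_weeks,
    n_above = report$n_above,
    n_below = report$n_below,
    n_within = report$n_within,
    n_missing = report$n_missing,
    n_outside = report$n_outside,
    fraction_outside = report$fraction_outside,
    expected_fraction = report$expected_fraction,
    first_above_date = if (is.na(report$first_above_date)) NULL else format(report$first_above_date),
    runs = if (nrow(report$runs) == 0) list() else {
      list(
        start_date = format(report$runs$start_date),
        length = report$runs$length
      )
    },
    summary = summary_row,
    weeks = list(
      week_start_date = format(report$weeks$week_start_date),
      observed = report$weeks$observed,
      flag = report$weeks$flag
    )
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}

#' Pandemic-era policy events used as plot annotations
#'
#' The three federal policy dates marked on the published figures: the
#' first state shelter-in-place (SIP) order, the date by which most
#' one-time Economic Impact Payments (EIP) had been sent, and the expiry of
#' the Pandemic Unemployment Compensation (PUC) supplement. They annotate
#' plots only and never enter any computation.
#'
#' @return Tibble with columns `name`, `date`, `kind`.
#' @export
policy_events <- function() {
  tibble::tibble(
    name = c("SIP orders begin", "EIP payments sent", "PUC expires"),
    date = as.Date(c("2020-03-19", "2020-04-17", "2020-07-31")),
    kind = c("onset", "payment", "expiry")
  )
}
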