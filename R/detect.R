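#' Classify observed target weeks against a prediction band
#'
#' Each observed week is flagged `above` if its value is strictly greater
#' than the band's upper bound, `below` if strictly less than the lower
#' bound, `missing` if suppressed, otherwise `within`. Ties at a bound
#' count as `within` (the conservative convention). The report also counts
#' exceedances, locates maximal serial runs of above-weeks, and records the
#' first above-flagged date — the quantity used to relate an excess to a
#' policy change.
#'
#' @param observed Aggregated `search_series` covering the target weeks.
#' @param band A `search_band` from [predict_band()] on the same week grid.
#' @return An `excess_report`: per-week flags plus totals, runs, and
#'   `first_above_date`. Use [tidy()] for the per-week table, [glance()] or
#'   [exceedance_vs_null()] for the summary row.
#' @export
classify_weeks <- function(observed, band) {
  stopifnot(
    is.data.frame(observed), is.data.frame(band),
    all(c("week_start_date", "value") %in% names(observed)),
    all(c("week_start_date", "point", "lower", "upper", "level") %in% names(band))
  )
  if (nrow(observed) != nrow(band) ||
    any(observed$week_start_date != band$week_start_date)) {
    abort("observed series and prediction band cover different week grids.")
  }
  v <- observed$value
  flag <- dplyr::case_when(
    is.na(v) ~ "missing",
    v > band$upper ~ "above",
    v < band$lower ~ "below",
    .default = "within"
  )
  weeks <- tibble::tibble(
    week_start_date = band$week_start_date,
    observed = v,
    point = band$point,
    lower = band$lower,
    upper = band$upper,
    flag = flag
  )
  level <- band$level[1]
  n_missing <- sum(flag == "missing")
  n_above <- sum(flag == "above")
  n_below <- sum(flag == "below")
  n_used <- nrow(weeks) - n_missing
  runs <- detect_runs(flag, weeks$week_start_date)
  structure(
    list(
      weeks = weeks,
      level = level,
      n_weeks = nrow(weeks),
      n_missing = n_missing,
      n_above = n_above,
      n_below = n_below,
      n_within = sum(flag == "within"),
      n_outside = n_above + n_below,
      fraction_outside = if (n_used > 0) (n_above + n_below) / n_used else NA_real_,
      expected_fraction = 1 - level,
      runs = runs,
      first_above_date = if (n_above > 0) {
        min(weeks$week_start_date[flag == "above"])
      } else {
        as.Date(NA)
      }
    ),
    class = "excess_report"
  )
}

#' Maximal serial runs of above-flagged weeks
#'
#' Serial clustering of exceedance weeks is the informal argument that an
#' excess is not a multiple-testing artifact: isolated false alarms land
#' singly, real excesses arrive in consecutive weeks. Runs are maximal and
#' disjoint; singletons count; a missing week breaks a run.
#'
#' @param flags Character vector of flags in date order
#'   (`above`/`within`/`below`/`missing`).
#' @param dates Matching `Date` vector of week starts.
#' @return Tibble with one row per run: `start_date`, `length`.
#' @export
detect_runs <- function(flags, dates) {
  stopifnot(length(flags) == length(dates))
  if (length(flags) == 0) {
    return(tibble::tibble(start_date = as.Date(character()), length = integer()))
  }
  r <- rle(flags == "above")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(
    start_date = as.Date(dates)[starts[keep]],
    length = r$lengths[keep]
  )
}

#' Compare observed exceedance to the null expectation
#'
#' Under a correctly calibrated band at level \eqn{1-\alpha}, a fraction
#' \eqn{\alpha} of null weeks is expected to fall outside (about 2.6 of 52
#' weeks at 95%). A result is "notable" when the outside count strictly
#' exceeds the integer ceiling of that expectation (more than 3 of 52
#' weeks); a count above the expectation but within its ceiling — 3 of 52,
#' say — is "marginal": slightly more than expected, but the kind of excess
#' prepandemic years also show. An exact binomial upper-tail probability is
#' reported as descriptive context only — weekly residuals may be serially
#' correlated, so it is never used as a gate.
#'
#' @param report An `excess_report`.
#' @return One-row tibble: counts, fractions, `notable`, `marginal`,
#'   `p_binomial`.
#' @export
exceedance_vs_null <- function(report) {
  stopifnot(inherits(report, "excess_report"))
  n_used <- report$n_weeks - report$n_missing
  if (n_used < 1) abort("report has no non-missing weeks.")
  expected_count <- report$expected_fraction * n_used
  exceeds <- report$fraction_outside > report$expected_fraction
  notable <- exceeds && report$n_outside > ceiling(expected_count)
  tibble::tibble(
    n_weeks = report$n_weeks,
    n_used = n_used,
    n_above = report$n_above,
    n_below = report$n_below,
    n_outside = report$n_outside,
    fraction_outside = report$fraction_outside,
    expected_fraction = report$expected_fraction,
    expected_count = expected_count,
    notable = notable,
    marginal = exceeds && !notable,
    p_binomial = pbinom(report$n_outside - 1, n_used, report$expected_fraction,
      lower.tail = FALSE
    )
  )
}

#' @export
print.excess_report <- function(x, ...) {
  cat(sprintf(
    "<excess_report> %d weeks at level %.2f\n", x$n_weeks, x$level
  ))
  cat(sprintf(
    "  above: %d, below: %d, within: %d, missing: %d\n",
    x$n_above, x$n_below, x$n_within, x$n_missing
  ))
  cat(sprintf(
    "  outside: %d/%d (%.1f%%), expected %.1f%%\n",
    x$n_outside, x$n_weeks - x$n_missing, 100 * x$fraction_outside,
    100 * x$expected_fraction
  ))
  if (nrow(x$runs) > 0) {
    cat(sprintf(
      "  %d above-run(s), longest %d week(s); first above week %s\n",
      nrow(x$runs), max(x$runs$length), format(x$first_above_date)
    ))
  } else {
    cat("  no above-flagged weeks\n")
  }
  invisible(x)
}

#' @describeIn classify_weeks Per-week flag table.
#' @param x An `excess_report`.
#' @param ... Unused.
#' @export
tidy.excess_report <- function(x, ...) {
  x$weeks
}

#' @describeIn classify_weeks One-row exceedance summary
#'   (same as [exceedance_vs_null()]).
#' @export
glance.excess_report <- function(x, ...) {
  exceedance_vs_null(x)
}
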