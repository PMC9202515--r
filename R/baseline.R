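#' Design matrix for the seasonal baseline regression
#'
#' Columns are an intercept, calendar time in fractional years since
#' `date_origin` (the linear secular-trend term), and the restricted cubic
#' spline expansion of week of year. Rows correspond to weeks with a
#' non-missing aggregated value; suppressed weeks are dropped, not imputed.
#'
#' @param series An aggregated `search_series`.
#' @param knots A `knot_set` for the week-of-year spline.
#' @param date_origin Origin of the calendar-time column; shifting it is an
#'   affine reparameterization absorbed by the intercept.
#' @return Numeric matrix with columns `(Intercept)`, `date_yrs`, `woy`, ...
#' @export
build_design <- function(series, knots, date_origin) {
  stopifnot(is.data.frame(series), all(c("week_start_date", "value") %in% names(series)))
  keep <- !is.na(series$value)
  if (!any(keep)) abort("series has no non-missing aggregated values.")
  dates <- series$week_start_date[keep]
  date_origin <- as_iso_date(date_origin, "date_origin")
  X <- cbind(
    `(Intercept)` = 1,
    date_yrs = as.numeric(dates - date_origin) / 365.25,
    rcs_design(week_of_year(dates), knots)
  )
  rownames(X) <- format(dates)
  X
}

#' Fit the prepandemic seasonal baseline by ordinary least squares
#'
#' Regresses the weekly aggregated search volume on a linear calendar-time
#' trend and a restricted cubic spline of week of year, by OLS. The fit
#' stores everything prediction needs without the training data:
#' coefficients, residual variance \eqn{s^2 = RSS/(n-p)}, residual degrees
#' of freedom, \eqn{(X^\top X)^{-1}}, the knots, and the date origin.
#'
#' @param series Aggregated training `search_series` (run
#'   [aggregate_replicates()] first).
#' @param knots Optional `knot_set`; default places knots at `percentiles`
#'   of the training weeks' week-of-year values.
#' @param percentiles Knot percentiles used when `knots` is `NULL`.
#' @param date_origin Origin for the trend term; default the first
#'   non-missing training week. Choice only rescales the intercept.
#' @return A `search_baseline` object; see [tidy()] and [glance()] methods,
#'   [predict_band()], and [residual_diagnostics()].
#' @examples
#' series <- generate_series(generator_params(end_date = "2019-12-31", seed = 1)) |>
#'   aggregate_replicates()
#' fit <- fit_baseline(series)
#' glance(fit)
#' @export
fit_baseline <- function(series, knots = NULL, percentiles = c(10, 50, 90),
                         date_origin = NULL) {
  stopifnot(is.data.frame(series), all(c("week_start_date", "value") %in% names(series)))
  keep <- !is.na(series$value)
  if (!any(keep)) {
    abort("series has no aggregated values; call aggregate_replicates() first.")
  }
  dates <- series$week_start_date[keep]
  if (is.null(date_origin)) date_origin <- dates[1]
  date_origin <- as_iso_date(date_origin, "date_origin")
  if (is.null(knots)) {
    knots <- knots_from_percentiles(week_of_year(dates), percentiles)
  } else if (is.numeric(knots)) {
    knots <- new_knot_set(knots)
  }

  X <- build_design(series, knots, date_origin)
  y <- series$value[keep]
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 2) {
    abort(sprintf("need at least %d non-missing weeks to fit %d coefficients.", p + 2, p))
  }
  df <- as.data.frame(X[, -1, drop = FALSE])
  df$y <- y
  fit <- lm(y ~ ., data = df)
  if (fit$rank < p) {
    abort("design matrix is rank deficient (collinear spline columns?).")
  }
  # summary.lm warns on essentially perfect fits; those are legitimate here
  # (noise-free synthetic series), so the warning is muffled
  sm <- suppressWarnings(summary(fit))
  res <- structure(
    list(
      coefficients = coef(fit),
      residual_variance = sm$sigma^2,
      residual_df = fit$df.residual,
      xtx_inverse = chol2inv(chol(crossprod(X))),
      knots = knots,
      date_origin = date_origin,
      adjusted_r2 = sm$adj.r.squared,
      training_window = range(dates),
      n_train = n,
      residuals = unname(fit$residuals),
      lm = fit
    ),
    class = "search_baseline"
  )
  dimnames(res$xtx_inverse) <- list(colnames(X), colnames(X))
  res
}

#' @export
print.search_baseline <- function(x, ...) {
  cat("<search_baseline> OLS seasonal baseline\n")
  cat(
    sprintf(
      "  %d training weeks (%s to %s), %d coefficients\n",
      x$n_train, format(x$training_window[1]), format(x$training_window[2]),
      length(x$coefficients)
    )
  )
  cat(sprintf(
    "  adjusted R^2 = %.3f, residual SD = %.3f on %d df\n",
    x$adjusted_r2, sqrt(x$residual_variance), x$residual_df
  ))
  cat(
    "  knots at week-of-year",
    paste(format(x$knots$knots), collapse = ", "), "\n"
  )
  invisible(x)
}

#' @describeIn fit_baseline Coefficient table (term, estimate, std.error,
#'   statistic, p.value).
#' @param x,object A `search_baseline`.
#' @param ... Unused.
#' @export
tidy.search_baseline <- function(x, ...) {
  if (!is.null(x$lm)) {
    sm <- summary(x$lm)$coefficients
    tibble::tibble(
      term = rownames(sm), estimate = unname(sm[, 1]),
      std.error = unname(sm[, 2]), statistic = unname(sm[, 3]),
      p.value = unname(sm[, 4])
    )
  } else {
    se <- sqrt(diag(x$xtx_inverse) * x$residual_variance)
    tibble::tibble(
      term = names(x$coefficients), estimate = unname(x$coefficients),
      std.error = unname(se),
      statistic = unname(x$coefficients / se),
      p.value = 2 * stats::pt(abs(unname(x$coefficients / se)),
        x$residual_df,
        lower.tail = FALSE
      )
    )
  }
}

#' @describeIn fit_baseline One-row model summary.
#' @export
glance.search_baseline <- function(x, ...) {
  tibble::tibble(
    adj.r.squared = x$adjusted_r2,
    sigma = sqrt(x$residual_variance),
    df.residual = x$residual_df,
    nobs = x$n_train,
    n_knots = length(x$knots$knots)
  )
}

#' Residual diagnostics for a fitted baseline
#'
#' A pure report on the training residuals: moments, lag-1 autocorrelation,
#' and a Shapiro-Wilk normality statistic. Violations are flagged, never
#' raised as errors: the baseline estimator remains plain OLS regardless
#' (matching the published analysis), and the flags surface when its
#' assumptions look doubtful. An essentially perfect fit (residual SD ~ 0)
#' is reported as degenerate.
#'
#' @param fit A `search_baseline`.
#' @return One-row tibble with residual moments, `lag1_autocorrelation`,
#'   Shapiro-Wilk `shapiro_w`/`shapiro_p`, and logical `flag_skewness`
#'   (|skewness| > 1), `flag_autocorrelation` (|lag-1| > 0.3), `degenerate`.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "search_baseline"))
  if (fit$residual_df < 10) abort("need residual_df >= 10 for diagnostics.")
  r <- fit$residuals
  n <- length(r)
  s <- sd(r)
  degenerate <- !is.finite(s) || s < sqrt(.Machine$double.eps) * max(1, abs(mean(r)))
  if (degenerate) {
    skew <- kurt <- ac1 <- 0
    sw <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    z <- (r - mean(r)) / s
    skew <- mean(z^3)
    kurt <- mean(z^4) - 3
    ac1 <- sum(z[-1] * z[-n]) / sum(z^2)
    sw <- suppressWarnings(shapiro.test(r))
  }
  tibble::tibble(
    n = n,
    mean = mean(r),
    sd = s,
    skewness = skew,
    excess_kurtosis = kurt,
    lag1_autocorrelation = ac1,
    shapiro_w = unname(sw$statistic),
    shapiro_p = sw$p.value,
    flag_skewness = !degenerate && abs(skew) > 1,
    flag_autocorrelation = !degenerate && abs(ac1) > 0.3,
    degenerate = degenerate
  )
}
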