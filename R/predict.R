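#' Out-of-sample prediction band for target weeks
#'
#' For each target week with design row \eqn{x_0}, the point prediction is
#' \eqn{x_0^\top \hat\beta} and the two-sided prediction interval at level
#' \eqn{1-\alpha} is
#' \deqn{x_0^\top \hat\beta \;\pm\; t_{1-\alpha/2,\,n-p}\; s\,
#'   \sqrt{1 + x_0^\top (X^\top X)^{-1} x_0}.}
#' The leading 1 under the square root makes this a prediction (not
#' confidence) interval: it bounds where an individual future weekly
#' observation is expected to fall, so about \eqn{\alpha} of null target
#' weeks land outside by design. Target rows are built exactly as in
#' training: same knots, same date origin. t (rather than normal) quantiles
#' are used because the residual variance is estimated.
#'
#' @param fit A `search_baseline`.
#' @param target_weeks `Date` vector of week starts (may — and typically
#'   does — lie outside the training window), or a `search_series` whose
#'   `week_start_date` column is used.
#' @param level Interval level in (0, 1); default 0.95.
#' @return A `search_band` tibble: `week_start_date`, `point`, `lower`,
#'   `upper`, `level`.
#' @examples
#' train <- generate_series(generator_params(end_date = "2019-12-31", seed = 1)) |>
#'   aggregate_replicates()
#' fit <- fit_baseline(train)
#' band <- predict_band(fit, week_grid("2020-01-01", "2020-12-31"))
#' head(band)
#' @export
predict_band <- function(fit, target_weeks, level = 0.95) {
  stopifnot(inherits(fit, "search_baseline"))
  if (is.data.frame(target_weeks)) target_weeks <- target_weeks$week_start_date
  target_weeks <- as_iso_date(target_weeks, "target_weeks")
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be a single probability strictly inside (0, 1).")
  }
  if (fit$residual_df <= 0) abort("fit has no residual degrees of freedom.")

  X0 <- cbind(
    1,
    as.numeric(target_weeks - fit$date_origin) / 365.25,
    rcs_design(week_of_year(target_weeks), fit$knots)
  )
  point <- drop(X0 %*% fit$coefficients)
  leverage <- rowSums((X0 %*% fit$xtx_inverse) * X0)
  half <- qt(1 - (1 - level) / 2, fit$residual_df) *
    sqrt(fit$residual_variance) * sqrt(1 + leverage)

  out <- tibble::tibble(
    week_start_date = target_weeks,
    point = point,
    lower = point - half,
    upper = point + half,
    level = level
  )
  class(out) <- c("search_band", class(out))
  out
}
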