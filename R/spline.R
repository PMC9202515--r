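#' Spline knots at empirical percentiles of week of year
#'
#' Knot locations are the empirical percentiles of the training week-of-year
#' values under the linear-interpolation quantile definition (R's type 7),
#' the default in the major statistics ecosystems. The conventional choice
#' for the seasonal baseline is knots at the 10th, 50th and 90th
#' percentiles, giving a 3-knot restricted cubic spline.
#'
#' @param week_values Numeric week-of-year values (at least 10 distinct).
#' @param percentiles Strictly increasing percentages in (0, 100).
#' @return A `knot_set`: list with `knots` (strictly increasing numeric) and
#'   `source_percentiles`.
#' @examples
#' knots_from_percentiles(rep(1:52, each = 3)) # knots 6, 26.5, 47
#' @export
knots_from_percentiles <- function(week_values, percentiles = c(10, 50, 90)) {
  week_values <- week_values[!is.na(week_values)]
  if (length(unique(week_values)) < 10) {
    abort("need at least 10 distinct week-of-year values to place knots.")
  }
  if (any(percentiles <= 0) || any(percentiles >= 100) ||
    any(diff(percentiles) <= 0)) {
    abort("`percentiles` must be strictly increasing and inside (0, 100).")
  }
  knots <- unname(quantile(week_values, percentiles / 100, type = 7))
  if (any(diff(knots) <= 0)) {
    abort(sprintf(
      "requested percentiles give coincident knots (%s); the week-of-year distribution is too concentrated.",
      paste(format(knots), collapse = ", ")
    ))
  }
  new_knot_set(knots, percentiles)
}

new_knot_set <- function(knots, source_percentiles = NULL) {
  if (length(knots) < 3) abort("a restricted cubic spline needs >= 3 knots.")
  if (any(diff(knots) <= 0)) abort("knots must be strictly increasing.")
  structure(
    list(knots = as.numeric(knots), source_percentiles = source_percentiles),
    class = "knot_set"
  )
}

#' @export
print.knot_set <- function(x, ...) {
  cat(
    "<knot_set>", length(x$knots), "knots at",
    paste(format(x$knots), collapse = ", ")
  )
  if (!is.null(x$source_percentiles)) {
    cat(
      " (percentiles",
      paste(format(x$source_percentiles), collapse = "/"), ")"
    )
  }
  cat("\n")
  invisible(x)
}

#' Restricted cubic spline design columns
#'
#' Harrell's truncated-power parameterization of the natural cubic spline:
#' for knots \eqn{t_1 < \dots < t_k}, the first column is \eqn{x} itself and
#' columns \eqn{j = 2, \dots, k-1} are
#' \deqn{[(x-t_{j-1})_+^3 - (x-t_{k-1})_+^3 (t_k-t_{j-1})/(t_k-t_{k-1})
#'       + (x-t_k)_+^3 (t_{k-1}-t_{j-1})/(t_k-t_{k-1})] / (t_k-t_1)^2,}
#' which is linear below \eqn{t_1} and above \eqn{t_k}, with continuous
#' first and second derivatives everywhere. Any rank-equivalent natural
#' spline basis gives identical fitted values downstream; this
#' parameterization is the de-facto standard in the regression-modelling
#' ecosystem and keeps coefficients on an interpretable scale.
#'
#' @param x Finite numeric vector (week-of-year values).
#' @param knots A `knot_set` or a strictly increasing numeric vector of
#'   length >= 3.
#' @return Numeric matrix, `length(x)` rows by `k - 1` columns, with
#'   columns named `woy`, `woy'`, `woy''`, ...
#' @export
rcs_design <- function(x, knots) {
  if (inherits(knots, "knot_set")) knots <- knots$knots
  if (length(knots) < 3) abort("a restricted cubic spline needs >= 3 knots.")
  if (any(!is.finite(x))) abort("`x` must be finite.")
  k <- length(knots)
  norm <- (knots[k] - knots[1])^2
  cub <- function(u) pmax(u, 0)^3
  nonlin <- vapply(seq_len(k - 2), function(j) {
    (cub(x - knots[j]) -
      cub(x - knots[k - 1]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1]) +
      cub(x - knots[k]) * (knots[k - 1] - knots[j]) / (knots[k] - knots[k - 1])
    ) / norm
  }, numeric(length(x)))
  out <- cbind(x, matrix(nonlin, nrow = length(x)))
  colnames(out) <- c("woy", paste0("woy_", seq_len(k - 2)))
  out
}
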