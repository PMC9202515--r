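#' Annotated prediction-band figure
#'
#' Reproduces the surveillance figure: observed weekly volumes as points,
#' the predicted seasonal curve, the prediction-interval ribbon, and dashed
#' vertical markers at the policy-event dates. Weeks outside the band are
#' highlighted when an `excess_report` is supplied to `autoplot()` via the
#' observed series' flags.
#'
#' @param object A `search_band`.
#' @param observed Optional aggregated `search_series` to draw as points
#'   (may extend before the band, e.g. the training years).
#' @param events Optional policy-event tibble (`name`, `date`, `kind`);
#'   default [policy_events()]. Use `NULL` to omit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.search_band <- function(object, observed = NULL,
                                 events = policy_events(), ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$week_start_date)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$point),
      colour = "steelblue4", linewidth = 0.6
    )
  if (!is.null(observed)) {
    obs <- observed[!is.na(observed$value), ]
    idx <- match(obs$week_start_date, object$week_start_date)
    flag <- ifelse(
      !is.na(idx) & obs$value > object$upper[pmax(idx, 1)] & !is.na(idx),
      "above",
      ifelse(!is.na(idx) & obs$value < object$lower[pmax(idx, 1)],
        "below", "within"
      )
    )
    flag[is.na(idx)] <- "within"
    p <- p + ggplot2::geom_point(
      data = transform(obs, flag = flag),
      ggplot2::aes(y = .data$value, colour = .data$flag),
      size = 1
    ) +
      ggplot2::scale_colour_manual(
        values = c(above = "firebrick", below = "darkorange", within = "grey30"),
        guide = "none"
      )
  }
  if (!is.null(events) && nrow(events) > 0) {
    p <- p +
      ggplot2::geom_vline(
        data = events, ggplot2::aes(xintercept = .data$date),
        linetype = "dashed", colour = "grey40"
      ) +
      ggplot2::annotate("text",
        x = events$date, y = Inf, label = events$name,
        angle = 90, vjust = -0.4, hjust = 1.1, size = 2.8, colour = "grey30"
      )
  }
  p + ggplot2::labs(
    x = NULL, y = "relative search volume",
    title = sprintf(
      "Weekly search volume with %g%% prediction interval",
      100 * object$level[1]
    )
  ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.search_band
#' @export
autoplot.excess_report <- function(object, events = policy_events(), ...) {
  w <- object$weeks
  band <- tibble::tibble(
    week_start_date = w$week_start_date, point = w$point,
    lower = w$lower, upper = w$upper, level = object$level
  )
  class(band) <- c("search_band", class(band))
  obs <- new_search_series(tibble::tibble(
    week_start_date = w$week_start_date,
    week_of_year = week_of_year(w$week_start_date),
    replicates = rep(list(numeric()), nrow(w)),
    value = w$observed
  ))
  autoplot(band, observed = obs, events = events)
}
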