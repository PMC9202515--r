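#' Configuration for an end-to-end surveillance run
#'
#' Bundles everything one pipeline run needs: where the series comes from
#' (a CSV path or a generator preset), the training and target windows, the
#' knot percentiles, the interval level, the replicate aggregator, the seed,
#' and the policy events to annotate plots with. The target window must
#' follow the training window; the two never overlap.
#'
#' @param input Optional path to a series CSV (long or aggregated schema);
#'   when `NULL` the series is generated from `params`.
#' @param params A [generator_params()] used when `input` is `NULL`.
#' @param excess Optional [excess_spec()] injected into generated data.
#' @param training_window,target_window Length-2 date vectors (start, end).
#' @param percentiles Knot percentiles for the week-of-year spline.
#' @param level Prediction-interval level.
#' @param aggregator `"mean"` or `"median"` replicate aggregation.
#' @param seed Integer seed driving all randomness in the run; overrides
#'   `params$seed` so one config field controls reproducibility.
#' @param events Policy-event tibble for plot annotation
#'   (default [policy_events()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL,
                            params = generator_params(),
                            excess = NULL,
                            training_window = c("2017-01-01", "2019-12-31"),
                            target_window = c("2020-01-01", "2020-12-31"),
                            percentiles = c(10, 50, 90),
                            level = 0.95,
                            aggregator = c("mean", "median"),
                            seed = 1L,
                            events = policy_events()) {
  aggregator <- match.arg(aggregator)
  training_window <- as_iso_date(training_window, "training_window")
  target_window <- as_iso_date(target_window, "target_window")
  if (length(training_window) != 2 || length(target_window) != 2) {
    abort("windows must be length-2 (start, end) date vectors.")
  }
  if (target_window[1] <= training_window[2]) {
    abort("target window must begin after the training window ends.")
  }
  structure(
    list(
      input = input, params = params, excess = excess,
      training_window = training_window, target_window = target_window,
      percentiles = percentiles, level = level, aggregator = aggregator,
      seed = as.integer(seed), events = events
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from JSON
#'
#' The JSON mirrors [pipeline_config()] fields; `params` and `excess` are
#' nested objects with [generator_params()] / [excess_spec()] fields, and a
#' `preset` string may replace `params`.
#'
#' @param path JSON config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- if (!is.null(j$preset)) {
    do.call(preset_params, c(list(outcome = j$preset), as.list(j$params)))
  } else if (!is.null(j$params)) {
    do.call(generator_params, as.list(j$params))
  } else {
    generator_params()
  }
  excess <- if (!is.null(j$excess)) do.call(excess_spec, as.list(j$excess))
  args <- list(
    input = j$input, params = params, excess = excess,
    seed = if (!is.null(j$seed)) j$seed else 1L
  )
  for (field in c(
    "training_window", "target_window", "percentiles", "level",
    "aggregator"
  )) {
    if (!is.null(j[[field]])) args[[field]] <- j[[field]]
  }
  do.call(pipeline_config, args)
}

#' Run the full surveillance pipeline
#'
#' Obtains the weekly series (from disk or the generator), aggregates
#' replicates, fits the seasonal OLS baseline on the training window,
#' predicts the band over the target window, classifies target weeks, and
#' writes the artifacts: `model.json`, `band.csv`, `flags.csv`,
#' `report.json`, and optionally `plot.png`. Deterministic given the config
#' seed.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for artifacts; created if needed. `NULL`
#'   skips writing and just returns the results.
#' @param write_plot Also render the annotated band figure to `plot.png`.
#' @param quiet Suppress progress messages (which go to standard error).
#' @return Invisibly, a list with `series`, `fit`, `band`, `report`.
#' @examples
#' cfg <- pipeline_config(seed = 7)
#' res <- run_pipeline(cfg, output_dir = NULL, quiet = TRUE)
#' res$report
#' @export
run_pipeline <- function(config, output_dir = NULL, write_plot = FALSE,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)

  if (!is.null(config$input)) {
    say("reading series from ", config$input)
    series <- read_series_csv(config$input)
  } else {
    say("generating synthetic series (seed ", config$seed, ")")
    params <- config$params
    params$seed <- config$seed
    series <- generate_series(params, config$excess)
  }
  if (all(is.na(series$value))) {
    if (all(lengths(series$replicates) == 0)) {
      abort("input series has neither replicates nor aggregated values.")
    }
    series <- aggregate_replicates(series, config$aggregator)
  }

  in_window <- function(d, w) d >= w[1] & d <= w[2]
  train <- dplyr::filter(
    series, in_window(.data$week_start_date, config$training_window)
  )
  target <- dplyr::filter(
    series, in_window(.data$week_start_date, config$target_window)
  )
  if (nrow(train) == 0) abort("no weeks fall inside the training window.")
  if (nrow(target) == 0) abort("no weeks fall inside the target window.")

  say("fitting baseline on ", nrow(train), " training weeks")
  fit <- fit_baseline(train, percentiles = config$percentiles)
  band <- predict_band(fit, target$week_start_date, level = config$level)
  report <- classify_weeks(target, band)
  say(
    "target weeks outside the ", format(100 * config$level),
    "% band: ", report$n_outside, "/", report$n_weeks
  )

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_baseline_json(fit, file.path(output_dir, "model.json"))
    write_band_csv(band, file.path(output_dir, "band.csv"))
    write_flags_csv(report, file.path(output_dir, "flags.csv"))
    write_report_json(report, file.path(output_dir, "report.json"))
    if (write_plot) {
      p <- autoplot(band, observed = series, events = config$events)
      ggplot2::ggsave(file.path(output_dir, "plot.png"), p,
        width = 9, height = 4.5, dpi = 150
      )
    }
    say("artifacts written to ", output_dir)
  }
  invisible(list(series = series, fit = fit, band = band, report = report))
}
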