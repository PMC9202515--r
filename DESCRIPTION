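Package: searchexcess
Title: Excess Search-Volume Detection with Seasonal Baselines and Prediction Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infoveillance tools for detecting excess weekly relative
    search volume against a prepandemic seasonal baseline. Fits an
    ordinary-least-squares model with a linear calendar-time trend and a
    restricted cubic spline on week of year, produces out-of-sample
    prediction intervals for a target year, flags exceedance weeks, and
    summarizes serial runs of above-interval weeks. Includes a calibrated
    synthetic-data generator that emulates replicate-sampled weekly search
    volumes so the full pipeline can be exercised and validated without
    access to a proprietary search API.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    readr,
    splines,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
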