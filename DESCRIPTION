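Package: driftdive
Title: Step-Wise Detection of Drift Dives and Buoyancy Trends from
    Abstracted Seal Dive Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects passive drift phases in broken-stick-abstracted
    time-depth profiles of diving marine predators using a step-wise
    rule-based filter (seven selection criteria on vertical speed, depth,
    fragment length, proportional duration, neighbouring-fragment
    behaviour and local time), and turns the retained drift rates into
    buoyancy trend estimates via quantile B-spline regression.
    Includes a re-implementation of the on-board broken-stick dive
    abstraction, a statistics-based derivation of the minimum drift
    fragment length, a sliding-window drift detector for high-resolution
    records, ARIMA-based time-series comparison with a simulated null
    distribution of correlation coefficients, and a synthetic dive-record
    simulator with ground-truth labels so the whole stack is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    quantreg,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
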