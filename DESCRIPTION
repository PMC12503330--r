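Package: aqmarkov
Title: Multi-State Markov Modelling of Weekly Air-Quality Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how regional air quality moves between
    categorical states over time. Converts daily PM2.5 concentrations to
    Air Quality Index (AQI) values through a configurable piecewise-linear
    breakpoint table, aggregates them into weekly averages with
    interpolation of sparse weeks, and classifies weeks as Good, Unhealthy
    or Very Unhealthy. Fits a panel-observed continuous-time three-state
    Markov model by maximum likelihood, with region covariates entering
    the transition intensities log-linearly, and derives hazard ratios
    with Wald confidence intervals, mean sojourn times with delta-method
    standard errors, and multi-week transition-probability matrices via
    the matrix exponential. Includes an exact (Gillespie-style) simulator
    of region-specific chains for validation studies and reporting helpers
    for counts, fractions, persistence curves and plots.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
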