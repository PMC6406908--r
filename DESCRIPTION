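Package: bibtrend
Title: Impact-Factor-Weighted Publication Trend Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and forecasting emerging research fields from
    journal-level publication counts. Computes impact-factor-weighted annual
    publication indices per field, their year-over-year fold changes (with a
    pseudo-count substitution rule for zero years), fits least-squares
    polynomial trends over sliding windows to extrapolate fold changes one to
    three years ahead, ranks fields into a predicted top-k, and backtests
    predictions against held-out years with exact binomial tests against a
    coincidence baseline. Includes a seeded synthetic corpus generator with
    planted trend regimes (stationary, emerging, burst, declining) for
    end-to-end validation without any network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
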