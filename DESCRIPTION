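Package: vo2overlap
Title: Test-Retest Similarity of Indirect Calorimetry Measures via
    Normal-Density Overlap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the day-to-day measurement error of gas-exchange
    indirect calorimetry (oxygen uptake, VO2, in L/min) as a univariate
    normal distribution whose standard deviation depends on the measured
    flow (differential measurement error), and reports the overlapping
    coefficient of two such distributions as the probability that two
    measures are the same. Ships device calibrations for the ParvoMedics
    2400 TrueOne metabolic cart and the Douglas bag recovered from
    published worked examples, fits new sigma(mu) calibrations from raw
    two-day test-retest data by polynomial regression, supports stacked
    (multi-subject) net-similarity analysis, generates synthetic two-day
    multi-workload protocols for validation, and includes a command-line
    interface for single comparisons, batch CSV analysis and calibration
    fitting.
License: MIT
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
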