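Package: tirpscope
Title: Associative Exploration of Frequent Time-Interval Patterns via
    Bidirectional Indexing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines frequent time-interval-related patterns (TIRPs) from
    databases of symbolic time intervals (STIs), builds forward and backward
    pair indices over the resulting enumeration tree, and supports
    associative exploration sessions in which a fixed STI sequence is
    extended earlier or later in time. Includes temporal abstraction of raw
    multivariate time series (state and gradient abstraction), pattern
    metrics (vertical and horizontal support, mean duration), plot-ready
    summaries (mean-presentation timelines, bubble charts, demographic
    breakdowns), a planted-pattern synthetic data generator, and JSON/CSV
    readers and writers for all artifact formats.
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
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
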