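Package: vaxquery
Title: Classify and Trend COVID-19 Vaccine Search-Query Logs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An infodemiology toolkit for studying online search behavior
    around COVID-19 vaccines. Provides a rules-based multi-label classifier
    that assigns search queries to five categories (availability,
    manufacturer, side effects and safety, myths and conspiracy beliefs,
    general/other) plus a pharmacy subcategory via a versioned keyword
    lexicon with spelling-variant handling; weekly volume-weighted category
    proportions and per-category linear time-trend regression; Google-Trends
    style relative-search-volume (0-100) normalization; a precision/recall
    evaluation harness against gold labels; and a seeded synthetic query-log
    generator with Zipfian query popularity and configurable linear category
    trends, so the whole pipeline is testable without proprietary search
    logs.
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
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
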