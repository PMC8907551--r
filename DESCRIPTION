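Package: mechmarker
Title: Mechanosensitivity and Dose-Response Analysis of Blood Biomarkers
    Under Ambulatory Load
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a blood biomarker is mechanosensitive
    and whether its response to a walking stress test depends on the magnitude
    of ambulatory load. Implements change-from-baseline transformations on an
    absolute (median-normalized) and a shifted relative scale, a
    random-intercept/random-slope response model fitted by restricted maximum
    likelihood with boundary likelihood-ratio tests for the variance
    components (mixture chi-square reference), a two-stage criteria gate for
    marker suitability, averaged Spearman correlation analyses with bootstrap
    Fisher-z inference, Monte Carlo power simulation for the crossover loading
    design, and a synthetic-data generator emulating the study layout
    (24 subjects, three load levels, five timepoints, duplicate assays).
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
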