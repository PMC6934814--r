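Package: dietlag
Title: Lagged Macronutrient Calculator for Ecological Correlation Series
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a linearized additive "calculator" equation relating yearly
    per-capita availabilities of five macronutrients (carbohydrates, protein,
    saturated, monounsaturated and polyunsaturated fat) to a yearly ecological
    correlation series, with an exhaustive grid search over per-nutrient
    precedence periods (lags in whole years).  Provides a three-criterion
    confidence procedure for the selected lags, a constrained grid search over
    diet compositions that minimises the predicted correlation while staying
    energetically close to historical mean consumption, synthetic-data
    generators with known ground truth, and report tables scaled to a common
    energy intake.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
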