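Package: gikit
Title: In Vitro Starch Digestion Kinetics and Estimated Glycemic Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning in vitro starch digestion assays into estimated
    glycemic index (eGI) predictions. Converts raw reducing-sugar absorbance
    readings into digestograms on either a percent-starch-digested or a
    carbohydrate-normalized reducing-sugar basis, characterizes digestion
    kinetics by logarithm-of-slope (LOS) plot analysis and first-order model
    fitting (single-fraction and multi-fraction parallel/sequential models),
    summarizes curves as area-under-curve statistics, calibrates and applies
    linear GI prediction equations, and validates predictions by relative
    error rate. A synthetic-data generator with known ground truth makes every
    stage testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
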