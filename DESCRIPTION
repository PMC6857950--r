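Package: chelonRI
Title: Reference Intervals and Biological Variation for Chelonian Clinical Pathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the inference pipeline used to establish hematology and
    plasma biochemistry reference intervals in free-ranging freshwater turtles:
    sample screening (inclusion rules, outlier detection, normality
    classification), variance-component decomposition of longitudinally sampled
    animals into within- and between-animal coefficients of variation, the
    index of individuality and reference change value, parametric and
    transformed-parametric population reference intervals with bootstrap
    confidence bounds, and demographic partition analysis with normality-gated
    test dispatch and AICc model selection. Ships a synthetic-data generator
    that reproduces the sampling structure of a two-site, two-year field study
    of Blanding's turtles so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
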