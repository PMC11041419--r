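Package: gvpatterns
Title: Glycemic Variability Pattern Recognition from Continuous Glucose Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts recurring blood-glucose fluctuation patterns from
    continuous glucose monitoring (CGM) traces by dynamic time warping (DTW)
    k-medoids clustering of overlapping fixed-duration windows, selects
    windowing hyperparameters with internal cluster validity indices and the
    number of patterns with the elbow method, summarises each patient as a
    "time in patterns" composition alongside classical glycemic-variability
    metrics (time in range, coefficient of variation), and groups patients
    into glycemic-variability profiles by compositional hierarchical
    clustering with downstream ANOVA and chi-square comparison of clinical
    variables. Includes a synthetic CGM cohort generator with known pattern
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
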