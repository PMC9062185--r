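Package: rmfm
Title: Relaxed Mean-Field Modelling of Whole-Brain Functional Connectivity and Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates regional neural activity on a structural connectome with
    the relaxed mean-field model (rMFM), converts it to BOLD signals through the
    Balloon-Windkessel hemodynamic model, and fits per-region recurrent
    connection strength (w) and subcortical input strength (I) to empirical
    functional connectivity. Includes the initial-parameter sensitivity grid,
    per-subject damped Gauss-Newton fitting, cohort-level group comparisons
    (Welch t-tests with Benjamini-Hochberg FDR control), polynomial age-trend
    fitting with shape classification, and a synthetic-cohort generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
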