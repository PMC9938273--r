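Package: crossfeed
Title: Single-Cell Growth Dynamics in Cross-Feeding Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mother-machine time-lapse experiments in which
    the microfluidic device is fed by a changing batch-culture environment, such as
    a chitin-degrader / cross-feeder community. Estimates instantaneous single-cell
    elongation rates from cell-length trajectories by robust local regression
    smoothing of log-lengths followed by sliding-window linear slopes with
    chi-squared quality filtering; accumulates channel-level biomass from
    per-timepoint mean rates; quantifies time-resolved condition contrasts with
    random-intercept mixed models and Welch tests; and measures growth-rate
    heterogeneity and bimodality (coefficient of variation, variance, Hartigan's
    dip test with a Monte-Carlo null). Includes a consumer-resource simulator of
    the degrader / cross-feeder batch environment and a lineage simulator that
    generates synthetic mother-machine length trajectories with division,
    mother-cell retention, daughter washout and measurement noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
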