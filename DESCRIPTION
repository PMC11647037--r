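Package: pulsarformer
Title: Transformer Attention Analysis of Pulsed Radiotherapy and
    Immunotherapy Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the temporal synergy between pulsed
    ultra-fractionated radiotherapy (PULSAR) and PD-L1 checkpoint blockade
    in murine tumor models. Provides a mechanistic synthetic-data generator
    (exponential growth, linear-quadratic radiation kill with lagged
    repopulation, time-lagged immune synergy, endpoint censoring, uniform
    augmentation), a token encoding of treatment schedules and sparse
    tumor-volume trajectories onto a 28-day axis, a minimal 536-parameter
    causal-masked encoder-decoder transformer trained with AdamW on masked
    L2 loss, and extraction of self- and cross-attention maps with
    group-differencing arithmetic that attributes attention changes to a
    single varied treatment factor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    tibble,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
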