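Package: hsqtl
Title: Bayesian Sparse-Regression QTL Mapping for Outbred Full-Sib Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: QTL detection in outbred full-sib ("cross pollinator") mapping
    populations using multi-marker linear models with a regularized horseshoe
    prior, projection-predictive variable selection, and PSIS-LOO model
    gating. Includes a pseudo-testcross cross simulator (Haldane/Kosambi map
    functions, two-way pseudo-testcross marker segregation, multi-QTL trait
    architectures), marker quality control (missingness, Mendelian
    segregation chi-square, collinearity pruning), linkage-map summary
    statistics, chlorophyll-fluorescence parameter arithmetic with trait
    correlation networks, and credible-interval QTL classification with
    percentage-variance-explained reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
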