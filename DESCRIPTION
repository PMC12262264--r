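Package: shade
Title: Hierarchical Bayesian Estimation of Directional Spatial Interaction Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates asymmetric, distance-resolved spatial associations
    (spatial interaction curves) between cell types in multiplexed tissue
    images. Models the conditional intensity of a target cell type given one
    or more source types through a logistic-regression approximation with
    dummy points, with interaction coefficients pooled hierarchically across
    images, patients, and cohorts and sampled by an adaptive Hamiltonian
    Monte Carlo (NUTS) sampler. Includes a synthetic multilevel point-pattern
    generator, G-cross envelope baselines, posterior summaries (credible
    bands, sign detection, group differences, heterogeneity), and
    conditional-intensity prediction with AUC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    splines,
    jsonlite,
    yaml,
    pROC
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
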