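Package: subconn
Title: Bayesian Structure Learning of Subcortical Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint Bayesian estimation of a binary conditional-independence
    network and partial-correlation strengths over subcortical regions of
    interest from resting-state BOLD time series. Per subject, a Markov chain
    Monte Carlo sampler explores Gaussian graphical model structures under a
    G-Wishart prior, summarising the posterior as edge-inclusion
    probabilities, expected partial correlations and expected network
    density; densities are then compared between groups with a two-tailed
    t-test. Includes ROI-level nuisance regression and high-pass filtering,
    and a synthetic two-group cohort generator with known sparse precision
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
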