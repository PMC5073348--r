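Package: groupsigma
Title: Structure Coefficients for Multi-Strategy Selection in
    Group-Structured Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency-dependent Moran and Wright-Fisher dynamics for finite
    populations fragmented into groups on a circle, with global mutation and
    isotropic migration. Computes the two structure coefficients (sigma1,
    sigma2) that govern which of S strategies is favoured under weak
    selection, by three independent routes: closed-form coalescent
    expressions valid for any population size, exact stationary analysis of
    the full Markov chain on tiny instances, and Monte-Carlo estimation from
    neutral simulations. Includes the weak-selection favourability condition
    for arbitrary payoff matrices, the two-strategy reduction, and the
    direct-reciprocity application (ALLC/ALLD/TFT critical cost-to-benefit
    ratio).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    jsonlite,
    rlang,
    igraph,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
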