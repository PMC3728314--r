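Package: sisnet
Title: Markovian SIS Dynamics, Quasi-Stationary Prevalence and Invasion
    Probability on Contact Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continuous-time Markovian
    susceptible-infectious-susceptible (SIS) dynamics on finite weighted
    directed contact networks. Provides exact finite-state computations of
    the quasi-stationary distribution (QSD), its decay parameter and the
    quasi-invasion probability from the sub-generator of the master
    equation; an event-driven (Gillespie) stochastic simulator with
    time-average prevalence and censored-fraction invasion estimators; the
    Harris graphical (percolation) representation with time reversal, used
    to verify the duality property realisation by realisation; and
    verification drivers for the exact prevalence-invasion relationship
    linking the two quantifiers on a network and its transpose.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
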