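Package: nmsis
Title: Non-Markovian SIS Epidemic Dynamics on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for susceptible-infected-susceptible (SIS) epidemic dynamics
    with arbitrary (non-exponential) infection and recovery waiting times on
    static networks. Provides waiting-time laws (Weibull, Beta, exponential)
    with hazards, survival functions and inverse-transform samplers; random
    graph generation and the spectral epidemic threshold; an exact
    event-driven stochastic simulator supporting two edge-activation
    mechanisms; an age-structured first-order mean-field integrator for
    transient dynamics; and the effective-rate machinery (renewal intensity,
    effective infection and recovery rates, quenched mean-field fixed points)
    that decides when a non-Markovian process is equivalent to a Markovian
    one. Results are returned as tibbles and plotted with ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
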