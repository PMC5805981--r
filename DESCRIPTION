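Package: pdmposc
Title: Piecewise Deterministic Markov Processes for Titration-Based Genetic Oscillators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of stochastic gene-expression dynamics in
    the non-adiabatic promoter-switching regime, built around titration-based
    oscillator circuits (activator-titration and repressor-titration motifs).
    Provides an exact Gillespie simulator of the full chemical master equation,
    a hybrid kinetic Monte Carlo simulator of the derived piecewise
    deterministic Markov process (PDMP), a fast-titration linearization with
    closed-form flows and analytic binding-time survival functions, an
    alternative deterministic limit built from mean waiting times, adiabatic
    (fast-switching) limit theory including quasi-stationary promoter
    distributions and a Bendixson no-limit-cycle certificate, stochastic cycle
    period detection and coherence statistics, and structural PDMP engines for
    extended mechanistic oscillator models with explicit mRNA dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
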