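Package: ifnabm
Title: Multi-Scale Stochastic Simulation of Cell Cultures Coupled by
    Diffusing Interferon
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based stochastic simulation of cell cultures whose cells
    communicate through secretion, diffusion and receptor binding of a
    cytokine. Provides a lattice-based stochastic diffusion algorithm using
    binomial emigration draws from a precomputed cumulative-binomial lookup
    table (with a normal-approximation fallback for large counts), calibration
    routines that link the lattice spacing, time step, diffusion coefficient
    and per-step emigration probability through point-source fits and an
    error-function mass balance, a synchronized Gillespie algorithm that
    accepts external state updates at preset times via memoryless redraw, and
    a dendritic-cell culture model in which infected cells secrete interferon
    that induces Rig-I expression in neighboring cells, including
    multiplicity-of-infection sweep experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    parallel,
    pracma,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
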