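Package: hscniche
Title: Hematopoietic Stem-Cell Niche Dynamics, Clonal Competition and
    Transplantation Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic compartment model of hematopoietic stem cells
    competing for a bone-marrow niche of finite capacity. Stem cells detach
    from the niche and become active, divide into a reattachable inactive
    state or differentiate; the package provides the multi-clone ordinary
    differential equation system with event-driven interventions
    (mobilization, preconditioning, single- and multi-dose
    transplantation), closed-form homeostatic equilibria with an invasion
    fitness that predicts competitive exclusion, comparative statics of the
    equilibrium, clonal abundance metrics contrasting niche and progenitor
    compartments, simulated-annealing parameter fitting against observed or
    synthetic time series, and a synthetic-data generator for testable
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
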