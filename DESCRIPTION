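Package: semiflexmc
Title: Generalized-Ensemble Monte Carlo for Dilute Semiflexible Polymers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained Monte Carlo simulation and analysis of dilute
    attractive semiflexible polymers. Implements bead-stick and bead-spring
    chains with truncated-shifted Lennard-Jones attraction, worm-like-chain
    bending stiffness and FENE bonds; canonical Metropolis, multicanonical
    flat-histogram and microcanonical-weight sampling with model-aware move
    sets (crankshaft, pivot, chain translation); canonical reweighting with
    jackknife errors; microcanonical entropy analysis with transition-order
    classification; nematic-like aggregation order parameters in periodic
    boxes; and topological knot identification of open chains via the
    Alexander polynomial evaluated at t = -1.1.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
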