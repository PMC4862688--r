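Package: swapfold
Title: Coarse-Grained Simulation and Prediction of Domain-Swapped
    Misfolding in Tandem Multidomain Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying domain-swapped misfolding of tandem
    repeat proteins with one-bead-per-residue structure-based (Go-type)
    models.  Builds single-domain and tandem-dimer contact models with
    swap-compatible duplicated contacts, enumerates circular-permutant
    cut sites and their frame-shifted contact sets and reaction
    coordinates, runs Langevin dynamics including first-passage
    misfolding campaigns and umbrella sampling with WHAM unbiasing, fits
    a single-sequence Wako-Saito-Munoz-Eaton Ising model with a midpoint
    strain penalty, predicts circular-permutant destabilization with an
    alchemical join-and-cut free energy model, and links permutant
    properties to misfolding propensity through rank-correlation
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
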