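Package: armdyn
Title: Arm-Specific Dynamics of Chromosome Rearrangement in Malaria Mosquitoes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for comparative physical mapping of
    polytene chromosome arms across Anopheles species. Implements a
    Monte-Carlo test for nonrandom co-localisation of homologous DNA
    markers inside polymorphic inversions of different species, a Bayesian
    hierarchical binomial intensity model (Metropolis-within-Gibbs, with a
    point-mass/hot/cold random-effect mixture) that estimates per
    region-pair sharing intensities, hotspot probabilities and the
    outside/inside connectivity ratio, a conserved synteny-block finder
    with full/partial conservation classification across three species,
    and a compound Poisson model of gene-order disruption rates per
    chromosome arm. A synthetic-data module generates marker maps,
    inversion layouts and rearranged gene orders with planted sharing
    intensities so the whole pipeline is testable without physical
    mapping data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
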