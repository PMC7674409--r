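Package: hexcolony
Title: Agent-Based Simulation of Cross-Feeding Bacterial Range Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based simulation of bacterial colony range expansion
    on a hexagonal lattice. Couples Fickian nutrient diffusion between lattice
    nodes to Monod growth kinetics for denitrifying strains that either
    compete for nitrate or cross-feed nitrite (producer/consumer), with an
    optional nitrite toxicity acting on the biomass yield. Colony expansion
    combines cell division, on-grid shoving toward the periphery and
    pseudo-three-dimensional stacking. Ancestral lineages are tracked from
    inoculation, supporting spatial population-genetic observables such as
    peripheral lineage counts, interspecies boundary counts, consumer branch
    statistics and the fraction of founders dominating final biomass, in
    homogeneous and obstacle-structured habitats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    png,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
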