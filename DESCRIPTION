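Package: invanet
Title: Structure and Robustness of Plant-Floral Visitor Networks in Invaded Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing bipartite plant-floral visitor interaction
    networks in plant communities invaded by alien species. Provides
    network-level structural metrics (NODF nestedness, H2' specialization,
    Barber bipartite modularity optimised by simulated annealing, robustness
    to species loss), degree-proportional (CE) null-model significance tests,
    species-level roles (normalized degree, species strength, nestedness
    contribution), Gower floral-trait similarity including hexagon chromatic
    coordinates for hymenopteran vision, origin-stratified extinction-scenario
    simulations with Hedges' g effect sizes, interaction sampling completeness
    via rarefaction and Chao1, and a synthetic-community generator that
    emulates invaded coastal dune communities for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, vegan, jsonlite
Suggests: testthat (>= 3.0.0), cluster, withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
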