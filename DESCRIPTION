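Package: demamp
Title: Demographic Amplification, Inertia Bounds and Phylogenetic
    Comparison of Plant Invasiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative demography of stage-structured plant
    populations. Computes stable growth rates and upper/lower bounds on
    demographic inertia (transient amplification and attenuation) from
    population projection matrices, applies structural quality control
    (irreducibility, primitivity, ergodicity), the seed-problem
    correction and post- to pre-reproductive census conversion, filters
    records with configurable inclusion rules, aggregates metrics to
    temporal-mean matrices and species-by-category means, and compares
    invasiveness categories with a Bayesian phylogenetic Gaussian mixed
    model fitted by Gibbs sampling with parameter expansion. Includes
    maximum-likelihood ancestral state reconstruction under Brownian
    motion, and seeded generators for synthetic life cycles, Yule
    phylogenies and full study datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
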