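Package: ebdims
Title: Elastic-Network Brownian Dynamics with Importance Sampling for
    Protein Transition Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained simulation of conformational transitions between
    two protein structures. Each residue is reduced to its C-alpha carbon and
    embedded in an essential-dynamics calibrated elastic network; Langevin
    dynamics in a stochastic bath is biased by a Maxwell-demon importance
    sampler that accepts stretches of unbiased dynamics only when a pairwise
    distance progress variable towards the target decreases. Companion
    ensemble-PCA tools project crystallographic ensembles and simulated
    pathways onto principal components, detect on-pathway intermediates,
    quantify forward/reverse pathway asymmetry, and build free-energy-style
    projection histograms. Includes normal mode analysis of the network,
    Monte-Carlo mode ensembles, and a deterministic synthetic hinge-protein
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
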