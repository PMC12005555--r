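Package: hicstruct
Title: Chromatin Structure Estimation from Hi-C Contact Maps with a
    Grid-Based Heteropolymer Model and a Graph Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates three-dimensional chromatin organization from Hi-C
    contact maps. Implements a theoretically informed coarse-grained (TICG)
    heteropolymer model sampled by Metropolis Monte Carlo on a contact grid,
    a maximum-entropy loop that fits the model's low-rank ("chromatin types")
    and Toeplitz ("ideal chromosome") interaction parameters to a target
    contact map, a synthetic-data generator that simulates realistic
    (contact map, parameter) training pairs, a sign-invariant graph
    attention network that predicts the interaction parameters directly
    from a contact map, and the contact-map reproducibility metrics
    (stratum-adjusted correlation, spectral Laplacian score, compartment
    PC1 correlation, distance-normalized RMSE) used to compare simulated
    and experimental maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
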