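Package: graphevo
Title: Eco-Evolutionary Dynamics and Phenotypic Differentiation on Spatial Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic individual-based simulation of birth, density-dependent
    death, mutation and migration for populations structured over spatial
    graphs, with co-evolving neutral and adaptive quantitative traits.
    Provides exact Gillespie simulation of the metapopulation, deterministic
    ordinary-differential-equation approximations of the population sizes, a
    finite-difference solver for the deterministic trait-distribution dynamics
    in heterogeneous habitats, an adaptive-dynamics analysis yielding the
    critical migration rate for local adaptation, landscape metrics (average
    path length, degree homogeneity, habitat assortativity), exhaustive
    enumeration of connected graphs up to isomorphism, and ensemble
    experiments relating graph topology to quantitative-trait differentiation
    (Q_ST) through standardized multivariate regression.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
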