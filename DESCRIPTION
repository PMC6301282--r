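Package: rlflux
Title: Constraint-Based Modelling of Rhamnolipid Production in Pseudomonas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for engineering and analysing constraint-based metabolic
    models of rhamnolipid-producing Pseudomonas strains. Provides model
    input/output (an SBML-FBC subset, COBRA-style JSON, tabular TSV), grafting
    of the rhamnosyltransferase (RhlA/RhlB/RhlC) reaction set onto a host
    model, flux balance analysis and flux variability analysis on a built-in
    linear-programming engine, the geometric flux balance centring algorithm
    that selects a unique representative optimal flux distribution,
    transcriptome-constrained condition-specific models via a log-scale
    bound-scaling rule, and the downstream statistical layer: differentially
    active reactions, elastic-net gene ranking and principal component
    analysis of flux matrices with contributions and squared cosines.
    A deterministic toy metabolic network and a synthetic two-group
    expression generator make the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    glmnet,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
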