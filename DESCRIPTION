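Package: crossfeedr
Title: Cross-Feeding Inference in Two-Member Microbial Communities by
    Flux Balance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constraint-based metabolic modelling toolkit for predicting
    metabolic interactions in defined two-member bacterial consortia, such
    as lactic acid bacteria co-cultures in milk.  Provides an SBML-subset
    and JSON model reader/writer, orthology-based draft model
    reconstruction by reaction transfer from reference models, flux
    balance analysis (FBA), parsimonious FBA and flux variability analysis
    on a compiled bounded-variable simplex solver, a balanced-growth
    community model with an equal-growth-rate coupling constraint, and a
    transport-knockout screen that classifies shared metabolites into
    essential and redundant cross-feeding interactions.  Includes a
    synthetic-data generator with planted ground-truth interactions and a
    genome assembly summary utility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    xml2,
    Biostrings,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
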