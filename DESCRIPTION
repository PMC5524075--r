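Package: fluxcond
Title: Condition-Specific Metabolic Flux Analysis from Expression Data
Version: 0.1.0
Authors@R:
    person("Flux", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates two-condition gene expression data with
    constraint-based metabolic models. Expression values are discretized
    per sample into trilevel states (high/moderate/low quartiles),
    aggregated per condition with a two-thirds majority rule, and mapped
    onto reactions through gene-protein-reaction logic. An iMAT
    mixed-integer program finds steady-state flux distributions
    maximizing agreement between flux activity and expression state;
    flux variability analysis at fixed maximal agreement and hit-and-run
    Monte-Carlo sampling characterize each condition's flux space.
    Differential reaction activity is called from sampled flux medians
    and summarized by hypergeometric pathway enrichment with
    Benjamini-Hochberg correction. A gene set enrichment analysis with a
    gene-set-randomization null (for small sample sizes) and a synthetic
    data generator with planted ground truth complete the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    xml2,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
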