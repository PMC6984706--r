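Package: ppifam
Title: Synthesis of Protein-Protein Interaction Network Families for
    Alignment Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Grows families of biologically related protein-protein
    interaction (PPI) networks along a user-defined phylogeny using four
    stochastic growth models (duplication-mutation-complementation,
    duplication with random mutation, crystal growth, and an incremental
    stickiness-index model), together with ground-truth functional
    orthology annotation and Gamma-distributed emulation of sequence
    similarity scores. Provides the statistical feature analyses used to
    validate synthetic networks against real PPI networks: power-law
    degree-exponent fitting, local clustering coefficients, the full
    2-5-node graphlet catalogue with automorphism orbits, graphlet degree
    distribution agreement (GDDA), and maximum-likelihood Gamma fits of
    similarity scores. A grid-search calibration module fits growth-model
    parameters to a reference feature summary, and preset benchmark
    suites (pairwise, 5-way, 8-way) can be generated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    ape,
    jsonlite,
    fitdistrplus,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
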