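Package: micronmf
Title: Poisson Non-Negative Matrix Factorization for Microbial Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Learns subcommunity structure in microbial count tables (OTU or
    functional-gene counts) by non-negative matrix factorization under a
    Poisson likelihood. Provides unsupervised Poisson NMF with
    Kullback-Leibler multiplicative updates and unit-sum type columns, a
    supervised NMF classifier built on non-negative identity-link Poisson
    regression, a cross-validated Wilcoxon rank-sum procedure for choosing
    the number of types, and a simulation suite including NMF-generative,
    zero-inflated, effect-size-mixture and Holling type II community-dynamics
    generators with a subcommunity-recovery loss and a permutation-based
    co-occurrence network baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    glmnet,
    cluster,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    SummarizedExperiment,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
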