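Package: cascnet
Title: Causal Structural Covariance Networks and Tremor-Type Classification
    from Brain Morphometry
Version: 0.1.0
Authors@R:
    person("cascnet", "developers", email = "cascnet@example.org",
           role = c("aut", "cre"))
Description: Tools for morphometric network analysis of tremor disorders.
    Implements vertex-wise general linear models with Monte-Carlo cluster
    correction, seed-based structural covariance network (SCN) interaction
    analysis with Gaussian random field correction, causal structural
    covariance networks (CaSCN) via signed-path Granger causality on
    disease-duration-ordered pseudo-time series, subcortical ANCOVA with
    FDR and Bonferroni post-hoc tests, forward-inference binomial decoding,
    and a LASSO-stability-selection multi-model classifier.  A synthetic
    cohort generator with planted duration-dependent cascade effects makes
    the whole pipeline testable without access to patient MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
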