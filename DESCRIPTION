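Package: metnull
Title: Constraint-Based Randomization Ensembles for Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Null-model ensembles for genome-scale metabolic networks. Genotypes
    are reaction subsets of a universe of biochemically valid reactions, sampled
    uniformly under nested constraints (fixed reaction count, metabolite-count
    cap, unblocked-reaction pool, flux-balance viability on minimal media) by
    reaction-swap Markov chain Monte Carlo. Includes a flux balance analysis
    core with blocked- and necessary-reaction detection built on an internal
    bounded-variable simplex solver, bipartite and currency-filtered metabolite
    graph statistics (clustering, path lengths, bow-tie decomposition), discrete
    power-law maximum-likelihood fitting of degree distributions, and a
    synthetic-universe generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "installed")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    boot,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
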