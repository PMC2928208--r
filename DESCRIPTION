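Package: ebPatterns
Title: Empirical Bayes Detection of Patterns of Differential Expression
    in Sequence Count Data
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Identifies arbitrary patterns of differential expression in
    count data from high-throughput sequencing experiments. Patterns are
    expressed as models: partitions of the samples into sets sharing
    identical negative-binomial distribution parameters. Per-tuple
    dispersions are estimated by quasi-likelihood, an empirical prior on
    the negative-binomial parameters is sampled from the whole dataset,
    and per-tuple posterior probabilities of each model are obtained by
    Monte-Carlo marginal likelihoods combined with iteratively estimated
    model priors. Includes negative-binomial simulators for pairwise and
    multi-group designs with known truth labels, FDR/ROC benchmarking
    utilities, and a Poisson-versus-negative-binomial overdispersion
    diagnostic.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    edgeR
biocViews: Bayesian, DifferentialExpression, Sequencing, RNASeq,
    MultipleComparison
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
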