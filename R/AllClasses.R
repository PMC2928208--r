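#' @import methods
#' @importFrom BiocGenerics counts
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats approx
#' @importFrom stats dpois median optimize pchisq rbinom rgamma rlnorm
#'   rnbinom rpois runif sd setNames
#' @importFrom utils read.delim write.table packageVersion head tail
#' @importFrom Rcpp sourceCpp
#' @useDynLib ebPatterns, .registration = TRUE
NULL

#' CountData: a tuple-by-sample table of sequencing counts
#'
#' `CountData` extends [SummarizedExperiment::SummarizedExperiment] and holds
#' a matrix of non-negative integer counts (tuples in rows, samples in
#' columns), per-sample library-size scaling factors, a condition label per
#' sample and a replicate-group label per sample. The replicate structure is
#' used only for dispersion estimation; the condition labels define the
#' candidate models (partitions of samples).
#'
#' A *tuple* is one row of counts: a single sequence tag, or an aggregate of
#' tags (for example all tags from one locus), with one count per sample.
#'
#' @slot .Data see [SummarizedExperiment::SummarizedExperiment]; the assay
#'   named `"counts"` holds the count matrix, `colData` holds `libSize`,
#'   `condition` and `replicate`.
#'
#' @seealso [CountData()] for construction, [readCounts()] to import a TSV.
#' @export
setClass("CountData", contains = "SummarizedExperiment")

.validCountData <- function(object) {
    msg <- NULL
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        return("assay 'counts' is missing")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (nrow(cts) < 1L || ncol(cts) < 2L)
        msg <- c(msg, "counts must have >= 1 tuple and >= 2 samples")
    if (anyNA(cts) || any(cts < 0) || any(cts != floor(cts)))
        msg <- c(msg, "counts must be non-negative integers")
    cd <- SummarizedExperiment::colData(object)
    for (f in c("libSize", "condition", "replicate"))
        if (!(f %in% colnames(cd)))
            msg <- c(msg, sprintf("colData field '%s' is missing", f))
    if ("libSize" %in% colnames(cd)) {
        ls <- cd$libSize
        if (anyNA(ls) || any(ls <= 0))
            msg <- c(msg, "library sizes must all be > 0")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "tuple identifiers (rownames) must be present and unique")
    if (is.null(msg)) TRUE else msg
}
setValidity("CountData", .validCountData)

#' ModelDefinition: one pattern of (non-)differential expression
#'
#' A model is a partition of the samples into non-overlapping, non-empty
#' sets; samples in the same set are assumed to share identical underlying
#' negative-binomial parameters for every tuple. The model of no
#' differential expression is the single-set partition; a pairwise
#' differential-expression model puts the two conditions in different sets.
#'
#' @slot name single character label (used in output column names).
#' @slot sets list of integer vectors of sample indices, forming a partition
#'   of `1:n`. Canonical form: members ascending within each set, sets
#'   ordered by smallest member.
#'
#' @seealso [validateModel()], [enumerateModels()]
#' @export
setClass("ModelDefinition",
    representation(name = "character", sets = "list"))

#' PriorSample: empirical prior draws for one model
#'
#' For each set \eqn{E_q} of a model, a sample \eqn{\Theta_q} of
#' (mean, dispersion) pairs estimated from randomly selected tuples of the
#' dataset, used as a Monte-Carlo prior in the marginal likelihood. Pairs
#' are drawn jointly per sampled tuple, so every \eqn{\Theta_q} of a model
#' has the same size, and by default the dispersion column is shared across
#' sets.
#'
#' @slot model the [ModelDefinition-class] the priors were built for.
#' @slot mu numeric matrix, draws x sets: per-set means per unit library size.
#' @slot phi numeric matrix, draws x sets: dispersions.
#' @slot provenance integer vector: row index of the tuple each draw was
#'   estimated from.
#'
#' @seealso [buildPriors()]
#' @export
setClass("PriorSample",
    representation(model = "ModelDefinition", mu = "matrix", phi = "matrix",
                   provenance = "integer"))

.validPriorSample <- function(object) {
    msg <- NULL
    m <- length(object@model@sets)
    if (nrow(object@mu) < 1L)
        msg <- c(msg, "prior sample must contain at least one draw")
    if (ncol(object@mu) != m || !all(dim(object@phi) == dim(object@mu)))
        msg <- c(msg, "mu/phi dimensions must be draws x model sets")
    if (any(object@mu <= 0))
        msg <- c(msg, "all prior means must be > 0")
    if (any(object@phi < 0))
        msg <- c(msg, "all prior dispersions must be >= 0")
    if (is.null(msg)) TRUE else msg
}
setValidity("PriorSample", .validPriorSample)

#' PosteriorTable: per-tuple posterior probabilities of each model
#'
#' Holds the log marginal likelihoods \eqn{\log P(D_c|M)}, the (converged)
#' model prior probabilities \eqn{P(M)}, the per-tuple posterior
#' probabilities \eqn{P(M|D_c)}, and the trajectory of the prior iteration.
#'
#' @slot logMarginals numeric matrix, tuples x models.
#' @slot modelPriors named numeric vector summing to 1.
#' @slot posteriors numeric matrix, tuples x models; rows sum to 1.
#' @slot iterations number of prior-update iterations performed.
#' @slot priorHistory matrix of prior vectors, one row per iteration
#'   (including the initial priors).
#' @slot converged logical: did the prior iteration converge.
#'
#' @seealso [estimateModelPriors()], [posteriorGivenPriors()],
#'   [combineModels()], [rankTuples()]
#' @export
setClass("PosteriorTable",
    representation(logMarginals = "matrix", modelPriors = "numeric",
                   posteriors = "matrix", iterations = "integer",
                   priorHistory = "matrix", converged = "logical"))

.validPosteriorTable <- function(object) {
    msg <- NULL
    if (!all(dim(object@posteriors) == dim(object@logMarginals)))
        msg <- c(msg, "posteriors and logMarginals dimensions differ")
    if (abs(sum(object@modelPriors) - 1) > 1e-8)
        msg <- c(msg, "model priors must sum to 1")
    if (any(object@modelPriors <= 0) || any(object@modelPriors >= 1)) {
        if (length(object@modelPriors) > 1L)
            msg <- c(msg, "model priors must lie in (0, 1)")
    }
    rs <- rowSums(object@posteriors)
    if (any(abs(rs - 1) > 1e-8))
        msg <- c(msg, "posterior rows must sum to 1")
    if (is.null(msg)) TRUE else msg
}
setValidity("PosteriorTable", .validPosteriorTable)
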