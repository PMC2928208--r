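.rowLogSumExp <- function(m) {
    mx <- apply(m, 1L, max)
    mx + log(rowSums(exp(m - mx)))
}

#' Posterior model probabilities at fixed model priors
#'
#' Bayes' rule per tuple: \eqn{P(M|D_c) \propto P(D_c|M)\,P(M)}, with the
#' scaling factor \eqn{P(D_c)} obtained by summing over all candidate
#' models. Computed in log space; each row of the result sums to 1.
#'
#' @param logMarginals numeric matrix, tuples x models, of log marginal
#'   likelihoods (column names are the model names).
#' @param modelPriors positive prior probabilities summing to 1, one per
#'   model.
#' @return numeric matrix of posterior probabilities, same shape as
#'   `logMarginals`.
#' @export
posteriorGivenPriors <- function(logMarginals, modelPriors) {
    logMarginals <- as.matrix(logMarginals)
    if (length(modelPriors) != ncol(logMarginals))
        stop("need one prior per model column")
    if (any(modelPriors <= 0) || abs(sum(modelPriors) - 1) > 1e-8)
        stop("model priors must be positive and sum to 1")
    lp <- sweep(logMarginals, 2L, log(modelPriors), "+")
    bad <- which(!is.finite(apply(lp, 1L, max)))
    if (length(bad) > 0L)
        stop("all model marginals are -Inf for tuple(s): ",
             paste(head(rownames(logMarginals)[bad], 5L), collapse = ", "))
    post <- exp(lp - .rowLogSumExp(lp))
    post / rowSums(post)
}

#' Estimate model prior probabilities by iterated mean posteriors
#'
#' Starting from initial priors (uniform by default), repeatedly computes
#' the per-tuple posteriors at the current priors and replaces each model's
#' prior with the mean of its posterior probability across all tuples,
#' until the largest prior change falls below `tol`. The converged priors
#' estimate the dataset-wide proportion of tuples following each model; in
#' practice the fixed point is insensitive to the initial choice. The full
#' prior trajectory is kept so the (known) positive-feedback tendency of
#' this scheme can be inspected.
#'
#' @inheritParams posteriorGivenPriors
#' @param initPriors initial prior vector (default uniform). Supply fixed,
#'   externally estimated priors with `maxIter = 0` to bypass iteration.
#' @param tol convergence tolerance on the largest prior change (default
#'   `1e-5`).
#' @param maxIter maximum iterations (default 1000); with `0`, the initial
#'   priors are used as-is.
#' @return a [PosteriorTable-class] object.
#' @export
estimateModelPriors <- function(logMarginals, initPriors = NULL, tol = 1e-5,
                                maxIter = 1000L) {
    logMarginals <- as.matrix(logMarginals)
    M <- ncol(logMarginals)
    if (is.null(colnames(logMarginals)))
        colnames(logMarginals) <- paste0("model_", seq_len(M))
    if (is.null(initPriors)) initPriors <- rep(1 / M, M)
    if (length(initPriors) != M || any(initPriors <= 0) ||
        abs(sum(initPriors) - 1) > 1e-8)
        stop("'initPriors' must be positive and sum to 1 over the models")
    pri <- as.numeric(initPriors)
    history <- matrix(pri, nrow = 1L,
                      dimnames = list(NULL, colnames(logMarginals)))
    post <- posteriorGivenPriors(logMarginals, pri)
    converged <- (maxIter == 0L)
    it <- 0L
    while (it < maxIter) {
        it <- it + 1L
        newpri <- colMeans(post)
        # guard against numerically degenerate zero priors
        newpri <- pmax(newpri, 1e-300)
        newpri <- newpri / sum(newpri)
        history <- rbind(history, newpri)
        delta <- max(abs(newpri - pri))
        pri <- newpri
        post <- posteriorGivenPriors(logMarginals, pri)
        if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
        warning(sprintf("model-prior iteration did not converge in %d steps",
                        maxIter))
    methods::new("PosteriorTable", logMarginals = logMarginals,
                 modelPriors = setNames(pri, colnames(logMarginals)),
                 posteriors = post, iterations = it,
                 priorHistory = unname(history) |>
                     `colnames<-`(colnames(logMarginals)),
                 converged = converged)
}

#' @rdname PosteriorTable-class
#' @export
setMethod("posteriors", "PosteriorTable", function(object) object@posteriors)

#' @rdname PosteriorTable-class
#' @export
setMethod("modelPriors", "PosteriorTable",
    function(object) object@modelPriors)

#' @rdname PosteriorTable-class
#' @export
setMethod("logMarginals", "PosteriorTable",
    function(object) object@logMarginals)

#' @rdname PosteriorTable-class
#' @export
setMethod("priorHistory", "PosteriorTable",
    function(object) object@priorHistory)

setMethod("show", "PosteriorTable", function(object) {
    cat(sprintf("PosteriorTable: %d tuples x %d models (%d iterations%s)\n",
                nrow(object@posteriors), ncol(object@posteriors),
                object@iterations,
                if (object@converged) "" else ", NOT converged"))
    cat("model priors:\n")
    print(round(object@modelPriors, 4))
})

#' Combine posterior probabilities of several models
#'
#' Because the models are mutually exclusive, the probability that a tuple
#' follows any model of a subset is the row-wise sum of the corresponding
#' posterior columns. Summing all models that describe differential
#' expression (every model except the single-set one) gives the probability
#' of differential expression of any type.
#'
#' @param object a [PosteriorTable-class] object.
#' @param modelSubset character vector of model (column) names.
#' @return named numeric vector of combined per-tuple probabilities.
#' @export
combineModels <- function(object, modelSubset) {
    stopifnot(methods::is(object, "PosteriorTable"))
    if (length(modelSubset) == 0L) stop("'modelSubset' must be non-empty")
    unknown <- setdiff(modelSubset, colnames(object@posteriors))
    if (length(unknown) > 0L)
        stop("unknown model(s): ", paste(unknown, collapse = ", "))
    p <- rowSums(object@posteriors[, modelSubset, drop = FALSE])
    setNames(pmin(p, 1), rownames(object@posteriors))
}

#' Rank tuples by a probability (or any score)
#'
#' Stable ordering with ties broken lexicographically by tuple id, so that
#' ranked lists are deterministic.
#'
#' @param probabilities named numeric vector (names are tuple ids).
#' @param descending rank largest first (default `TRUE`).
#' @return data.frame with columns `tuple`, `score`, `rank`.
#' @export
rankTuples <- function(probabilities, descending = TRUE) {
    if (is.null(names(probabilities)))
        names(probabilities) <- seq_along(probabilities)
    o <- order(if (descending) -probabilities else probabilities,
               names(probabilities), method = "radix")
    data.frame(tuple = names(probabilities)[o],
               score = unname(probabilities[o]),
               rank = seq_along(o))
}
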