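.PHI_MIN <- 1e-6
.PHI_MAX <- 1e3
.MU_FLOOR <- 1e-8

# run code with a local RNG state seeded by `seed`, restoring the caller's
# stream afterwards so package functions never perturb user randomness
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else rm(".Random.seed", envir = globalenv())
    })
    force(code)
}

#' Quasi-likelihood dispersion estimate for one tuple
#'
#' Estimates the per-tuple dispersion under the replicate structure by
#' choosing `phi` so that the negative-binomial deviance of the
#' replicate-group fit equals `n - 1` (`n` samples), alternating with
#' maximum-likelihood re-estimation of the per-replicate-group means at
#' fixed `phi` until `phi` stabilises. Group means are initialised as the
#' mean of `u/l` within each group. When the data are under-dispersed
#' relative to Poisson the equation has no positive root and `phi` is
#' clamped at `phiMin`; tuples that stay over-dispersed beyond `phiMax` are
#' clamped there.
#'
#' @param object a [CountData-class] object.
#' @param tuple row index or id of the tuple to fit.
#' @param phiMin,phiMax dispersion bounds (defaults `1e-6`, `1e3`).
#' @param tol relative convergence tolerance on `phi` (default `1e-4`).
#' @param maxIter maximum alternation steps (default 50).
#' @return a list with `phi`, `mu` (fitted per-replicate-group means per
#'   unit library size, in replicate-group level order), `iterations`,
#'   `converged`, and `reason` (`"root"`, `"deviance below target at
#'   phi_min"`, `"clamped at phi_max"` or `"max iterations"`).
#' @seealso [buildPriors()] which applies this over sampled tuples;
#'   [qlDeviance()] for the deviance itself.
#' @export
estimateDispersion <- function(object, tuple, phiMin = .PHI_MIN,
                               phiMax = .PHI_MAX, tol = 1e-4, maxIter = 50L) {
    stopifnot(methods::is(object, "CountData"))
    u <- counts(object)[tuple, ]
    rep <- .repCodes(object)
    fit <- cpp_fit_dispersion(as.integer(u), as.numeric(libSizes(object)),
                              rep$codes, rep$n, phiMin, phiMax, tol,
                              as.integer(maxIter))
    names(fit$mu) <- levels(factor(replicateGroups(object)))
    fit
}

#' Quasi-likelihood deviance of a tuple at a given dispersion
#'
#' The statistic whose root (in `phi`, with target `n - 1`) defines the
#' quasi-likelihood dispersion estimate; exposed for diagnostics. It is
#' non-increasing in `phi`, equal to the Poisson deviance at `phi = 0`, and
#' tends to 0 as `phi` grows, so the root is unique when it exists.
#'
#' @inheritParams estimateDispersion
#' @param muGroups fitted mean per replicate group (per unit library size),
#'   in replicate-group level order.
#' @param phi dispersion at which to evaluate the deviance.
#' @return the deviance (a single number).
#' @export
qlDeviance <- function(object, tuple, muGroups, phi) {
    u <- counts(object)[tuple, ]
    rep <- .repCodes(object)
    cpp_ql_deviance(as.integer(u), as.numeric(libSizes(object)),
                    rep$codes, as.numeric(muGroups), phi)
}

#' Maximum-likelihood per-set means at fixed dispersion
#'
#' For each set \eqn{E_q} of a model, the value of `mu` maximising
#' \eqn{\prod_{i \in E_q} P(u_{ic};\, l_i, \phi, \mu)} at the given
#' dispersion, found as the root of the score equation. At `phi = 0` this is
#' the Poisson closed form `sum(u)/sum(l)`. Sets whose counts are all zero
#' return `muFloor` so the negative-binomial pmf stays defined downstream.
#'
#' @inheritParams estimateDispersion
#' @param model a validated [ModelDefinition-class].
#' @param phi the (fixed) dispersion.
#' @param muFloor lower floor for the returned means (default `1e-8`).
#' @return numeric vector of per-set means, one per model set.
#' @export
estimateSetMeans <- function(object, tuple, model, phi,
                             muFloor = .MU_FLOOR) {
    stopifnot(methods::is(object, "CountData"))
    model <- validateModel(model, ncol(object))
    u <- counts(object)[tuple, ]
    l <- as.numeric(libSizes(object))
    vapply(modelSets(model), function(s) {
        m <- cpp_nb_mean_mle(as.integer(u[s]), l[s], phi)
        max(m, muFloor)
    }, 1)
}

#' Build empirical prior samples for one or more models
#'
#' Samples `sampleSize` tuples uniformly at random without replacement
#' (all tuples when `sampleSize` is at least the number of tuples), and for
#' each sampled tuple estimates its dispersion by quasi-likelihood under the
#' replicate structure ([estimateDispersion()]) and then, for every set of
#' every model, the maximum-likelihood mean at that fixed dispersion
#' ([estimateSetMeans()]). The resulting (mean, dispersion) pairs form the
#' Monte-Carlo prior \eqn{\Theta_q} of each model set. The dispersion fit is
#' shared across models and sets (the dispersion of a tuple is treated as
#' constant across sets of samples); set `perSetDispersion = TRUE` to
#' re-estimate it within each model set instead (restricting the data and
#' replicate structure to that set), a variant that in practice changes
#' results very little.
#'
#' @param object a [CountData-class] object.
#' @param models a [ModelDefinition-class] or a list of them.
#' @param sampleSize number of tuples to sample (default 5000).
#' @param seed integer seed making the tuple sample reproducible.
#' @param phiMin,phiMax,tol,maxIter dispersion-fit controls, see
#'   [estimateDispersion()].
#' @param muFloor floor on estimated means, see [estimateSetMeans()].
#' @param perSetDispersion logical; see Details above.
#' @return a [PriorSample-class] (or a named list of them when `models` is a
#'   list), each with one (mu, phi) pair per sampled tuple per set.
#' @examples
#' sim <- simulatePairwiseRandomDispersion(nTuples = 200, seed = 1)
#' mods <- enumerateModels(conditions(sim))
#' pri <- buildPriors(sim, mods, sampleSize = 50, seed = 2)
#' dim(pri[[2]]@mu)  # 50 draws x 2 sets
#' @export
buildPriors <- function(object, models, sampleSize = 5000L, seed = 1L,
                        phiMin = .PHI_MIN, phiMax = .PHI_MAX, tol = 1e-4,
                        maxIter = 50L, muFloor = .MU_FLOOR,
                        perSetDispersion = FALSE) {
    stopifnot(methods::is(object, "CountData"))
    single <- methods::is(models, "ModelDefinition")
    if (single) models <- list(models)
    models <- lapply(models, validateModel, nSamples = ncol(object))
    if (sampleSize < 1L) stop("'sampleSize' must be >= 1")
    nT <- nrow(object)
    idx <- if (sampleSize >= nT) seq_len(nT) else
        sort(.withSeed(seed, sample.int(nT, sampleSize)))
    rep <- .repCodes(object)
    res <- cpp_build_priors(counts(object), as.numeric(libSizes(object)),
                            rep$codes, rep$n,
                            lapply(models, function(m)
                                lapply(modelSets(m), as.integer)),
                            as.integer(idx), phiMin, phiMax, tol,
                            as.integer(maxIter), muFloor, perSetDispersion)
    out <- lapply(seq_along(models), function(j)
        methods::new("PriorSample", model = models[[j]],
                     mu = res$mu[[j]], phi = res$phi[[j]],
                     provenance = as.integer(idx)))
    names(out) <- vapply(models, modelName, "")
    if (single) out[[1L]] else out
}

setMethod("show", "PriorSample", function(object) {
    cat(sprintf("PriorSample for model '%s': %d draws x %d set(s)\n",
                modelName(object@model), nrow(object@mu), ncol(object@mu)))
    cat(sprintf("  dispersion: median %.4g [%.4g, %.4g]\n",
                median(object@phi[, 1L]), min(object@phi[, 1L]),
                max(object@phi[, 1L])))
})
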