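#' Negative binomial log probability mass
#'
#' Log-probability of observing count `u` in a library of size `l` when the
#' underlying expression rate per unit library size is `mu` and the
#' dispersion is `phi`: the count has mean `l*mu` and variance
#' `l*mu*(1 + l*mu*phi)`. `phi = 0` is evaluated exactly as the Poisson
#' limit. Arguments are recycled to a common length.
#'
#' @param u non-negative count(s).
#' @param libSize positive library size(s).
#' @param mu positive mean rate(s) per unit library size.
#' @param phi dispersion(s), `>= 0`.
#' @return log-probabilities, same length as the recycled arguments.
#' @examples
#' nbLogPmf(0, 1, 1, 1)            # log(1/2)
#' nbLogPmf(3, 1, 1, 1)            # geometric: log(2^-4)
#' @export
nbLogPmf <- function(u, libSize, mu, phi) {
    n <- max(length(u), length(libSize), length(mu), length(phi))
    u <- rep_len(as.numeric(u), n)
    libSize <- rep_len(as.numeric(libSize), n)
    mu <- rep_len(as.numeric(mu), n)
    phi <- rep_len(as.numeric(phi), n)
    if (any(u < 0) || any(u != floor(u))) stop("'u' must be integer >= 0")
    if (any(libSize <= 0)) stop("'libSize' must be > 0")
    if (any(mu <= 0)) stop("'mu' must be > 0")
    if (any(phi < 0)) stop("'phi' must be >= 0")
    cpp_nb_log_pmf(u, libSize, mu, phi)
}

# prior matrices for a model in draws x sets layout, with basic checks
.priorMatrices <- function(priors, model) {
    stopifnot(methods::is(priors, "PriorSample"))
    if (!identical(lapply(priors@model@sets, as.integer),
                   lapply(model@sets, as.integer)))
        stop("prior sample was built for model '", modelName(priors@model),
             "', not '", modelName(model), "'")
    if (nrow(priors@mu) < 1L) stop("empty prior sample")
    list(mu = priors@mu, phi = priors@phi)
}

#' Monte-Carlo marginal log-likelihood of tuples under a model
#'
#' Approximates, for each tuple, the log marginal likelihood
#' \deqn{\log P(D_c|M) = \sum_q \log \frac{1}{|\Theta_q|} \sum_{\theta \in
#'   \Theta_q} \prod_{i \in E_q} P(u_{ic};\, l_i, \theta)}
#' by averaging the within-set likelihood over the empirical prior draws
#' \eqn{\Theta_q}, independently for each set (the set-level parameters are
#' treated as independent across sets). Computation is carried out in log
#' space with log-sum-exp over the prior draws.
#'
#' @param object a [CountData-class] object (all tuples are evaluated; use
#'   `tuples` to restrict).
#' @param model a validated [ModelDefinition-class].
#' @param priors a [PriorSample-class] built for `model` (see
#'   [buildPriors()]).
#' @param tuples optional integer or character index of tuples to evaluate.
#' @return named numeric vector of per-tuple log marginal likelihoods.
#' @seealso [buildPriors()], [posteriorGivenPriors()]
#' @export
marginalLikelihood <- function(object, model, priors, tuples = NULL) {
    stopifnot(methods::is(object, "CountData"))
    model <- validateModel(model, ncol(object))
    pm <- .priorMatrices(priors, model)
    cts <- counts(object)
    if (!is.null(tuples)) cts <- cts[tuples, , drop = FALSE]
    ll <- cpp_marginal_loglik(cts, as.numeric(libSizes(object)),
                              lapply(modelSets(model), as.integer),
                              pm$mu, pm$phi)
    setNames(ll, rownames(cts))
}
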