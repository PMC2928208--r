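# Negative-binomial count matrix for a tuples x samples mean matrix and
# per-tuple dispersions (phi = 0 tuples drawn Poisson)
.rnbMatrix <- function(meanMat, phi) {
    T <- nrow(meanMat); n <- ncol(meanMat)
    sz <- rep(1 / phi, times = n)
    mu <- as.vector(meanMat)
    out <- numeric(T * n)
    pois <- !is.finite(sz)
    if (any(!pois))
        out[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = sz[!pois])
    if (any(pois))
        out[pois] <- rpois(sum(pois), mu[pois])
    matrix(as.integer(out), T, n)
}

.tupleIds <- function(n) sprintf("tuple_%0*d", nchar(n), seq_len(n))

# default surrogate for the per-tuple expression rate lambda: a heavy-tailed
# log-normal emulating tag-level abundances in SAGE-scale libraries (most
# distinct tags seen once or twice; median simulated count ~2 at library
# size 6e4, upper tail reaching counts of ~1e4)
.rlambda <- function(n, meanlog = log(3e-5), sdlog = 2) {
    rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

#' Simulate a pairwise design with random per-tuple dispersions
#'
#' Two conditions `A` (`n1` libraries) and `B` (`n2` libraries). Library
#' sizes are drawn uniformly between `libSizeRange[1]` and `libSizeRange[2]`
#' and rounded to integers; per-tuple dispersions are drawn from a gamma
#' distribution (default shape 0.85, scale 0.5); per-tuple expression rates
#' `lambda` come from a heavy-tailed log-normal surrogate distribution (or a
#' user-supplied pool, resampled per tuple). Non-differentially-expressed
#' tuples have mean `lambda * l_i` in every library. A fixed number
#' (`deFraction * nTuples`) of tuples are differentially expressed with
#' means `lambda * l_i / b` in one condition and `lambda * l_i * b` in the
#' other, the direction chosen at random per tuple, so both over- and
#' under-expression occur. Truth labels are exact in count and randomly
#' placed among the tuples.
#'
#' @param nTuples number of tuples (default 10000).
#' @param n1,n2 libraries per condition (default 2 and 2).
#' @param b fold parameter `> 1` (default 4): DE tuples differ by `b^2`
#'   between conditions.
#' @param deFraction fraction of DE tuples (default 0.1).
#' @param dispersionShape,dispersionScale gamma parameters for the per-tuple
#'   dispersions (defaults 0.85 and 0.5); or supply `phi` to fix the
#'   dispersion for all tuples (`0` simulates Poisson data).
#' @param phi optional fixed dispersion overriding the gamma draw.
#' @param lambda optional pool of expression rates to resample instead of
#'   the log-normal surrogate.
#' @param lambdaMeanlog,lambdaSdlog log-normal parameters of the surrogate
#'   rate distribution (defaults `log(3e-5)` and 2, emulating
#'   tag-level SAGE abundances: median count of ~2 at these library sizes
#'   with a heavy upper tail).
#' @param libSizeRange uniform bounds for library sizes (default
#'   `c(30000, 90000)`).
#' @param seed integer seed; the output is fully determined by it.
#' @return a [CountData-class] object whose `rowData` records per-tuple
#'   truth: `pattern` (`"none"` or `"{A}{B}"`), `lambda`, `phi`, and
#'   `direction` (+1: condition B up; -1: condition A up; 0: non-DE).
#' @examples
#' sim <- simulatePairwiseRandomDispersion(nTuples = 1000, seed = 7)
#' table(SummarizedExperiment::rowData(sim)$pattern)
#' @export
simulatePairwiseRandomDispersion <- function(nTuples = 10000L, n1 = 2L,
        n2 = 2L, b = 4, deFraction = 0.1, dispersionShape = 0.85,
        dispersionScale = 0.5, phi = NULL, lambda = NULL,
        lambdaMeanlog = log(3e-5), lambdaSdlog = 2,
        libSizeRange = c(30000, 90000), seed = 1L) {
    stopifnot(nTuples >= 1, n1 >= 1, n2 >= 1, b >= 1,
              deFraction >= 0, deFraction <= 1)
    .withSeed(seed, {
        n <- n1 + n2
        l <- round(runif(n, libSizeRange[1L], libSizeRange[2L]))
        lam <- if (is.null(lambda))
            .rlambda(nTuples, lambdaMeanlog, lambdaSdlog)
        else sample(lambda, nTuples, replace = TRUE)
        ph <- if (is.null(phi))
            rgamma(nTuples, shape = dispersionShape, scale = dispersionScale)
        else rep(phi, nTuples)
        nDE <- round(deFraction * nTuples)
        pattern <- sample(rep(c("{A}{B}", "none"), c(nDE, nTuples - nDE)))
        de <- pattern != "none"
        direction <- integer(nTuples)
        direction[de] <- sample(c(-1L, 1L), nDE, replace = TRUE)
        fold <- matrix(1, nTuples, n)
        condB <- c(rep(FALSE, n1), rep(TRUE, n2))
        fold[de, !condB] <- ifelse(direction[de] > 0, 1 / b, b)
        fold[de, condB] <- ifelse(direction[de] > 0, b, 1 / b)
        meanMat <- (lam %o% l) * fold
        cts <- .rnbMatrix(meanMat, ph)
        rownames(cts) <- .tupleIds(nTuples)
        colnames(cts) <- c(paste0("A", seq_len(n1)), paste0("B", seq_len(n2)))
        CountData(cts, conditions = rep(c("A", "B"), c(n1, n2)),
                  libSizes = l,
                  rowData = S4Vectors::DataFrame(
                      pattern = pattern, lambda = lam, phi = ph,
                      direction = direction))
    })
}

#' Simulate a ten-library pairwise design with fixed dispersion
#'
#' Ten libraries (five per condition) with library sizes drawn as in
#' [simulatePairwiseRandomDispersion()]. All tuples share the dispersion
#' `phi` and the expression rate `lambda` (default `2e-4`). Half of the
#' tuples (exactly) are differentially expressed: their mean stays
#' `lambda * l_i` in libraries 1-5 (condition `A`) and is `b * lambda * l_i`
#' in libraries 6-10 (condition `B`), so all differential expression is
#' over-expression of condition `B`.
#'
#' @param nTuples total tuples (default 10000; half are DE).
#' @param phi fixed dispersion for every tuple (`0.17`, `0.42` or `0.95` in
#'   the benchmark settings; `0` gives Poisson data).
#' @param lambda common expression rate (default `2e-4`).
#' @param b fold change of the over-expressed condition (default 4).
#' @inheritParams simulatePairwiseRandomDispersion
#' @return a [CountData-class] object with truth labels as in
#'   [simulatePairwiseRandomDispersion()] (`direction` is always `+1` for DE
#'   tuples here).
#' @export
simulateFixedDispersion <- function(nTuples = 10000L, phi = 0.42,
        lambda = 2e-4, b = 4, libSizeRange = c(30000, 90000), seed = 1L) {
    stopifnot(nTuples >= 2, phi >= 0, lambda > 0, b >= 1)
    .withSeed(seed, {
        n <- 10L
        l <- round(runif(n, libSizeRange[1L], libSizeRange[2L]))
        nDE <- floor(nTuples / 2)
        pattern <- sample(rep(c("{A}{B}", "none"), c(nDE, nTuples - nDE)))
        de <- pattern != "none"
        fold <- matrix(1, nTuples, n)
        fold[de, 6:10] <- b
        meanMat <- (rep(lambda, nTuples) %o% l) * fold
        cts <- .rnbMatrix(meanMat, rep(phi, nTuples))
        rownames(cts) <- .tupleIds(nTuples)
        colnames(cts) <- c(paste0("A", 1:5), paste0("B", 1:5))
        CountData(cts, conditions = rep(c("A", "B"), each = 5L),
                  libSizes = l,
                  rowData = S4Vectors::DataFrame(
                      pattern = pattern, lambda = rep(lambda, nTuples),
                      phi = rep(phi, nTuples),
                      direction = ifelse(de, 1L, 0L)))
    })
}

#' Simulate a three-condition multi-group design
#'
#' Conditions `A`, `B` and `C` with `n` libraries each (3n libraries in
#' total); library sizes, dispersions and expression rates as in
#' [simulatePairwiseRandomDispersion()]. Exactly `perPattern` tuples follow
#' each of the four differential-expression patterns: three patterns in
#' which one condition differs from the other two (means `lambda*l/b` for
#' the pair and `lambda*l*b` for the singleton, or the reverse, chosen at
#' random per tuple), and one all-different pattern in which the three
#' conditions play roles `X1`, `X2`, `X3` (means `lambda*l`,
#' `lambda*l/(2b)` and `lambda*l*2b`), randomly allocated per tuple. The
#' remaining tuples are not differentially expressed.
#'
#' @param n libraries per condition (default 2).
#' @param perPattern DE tuples per pattern (default 500, giving 2000 DE
#'   tuples of 10000).
#' @param b fold parameter (default 8).
#' @inheritParams simulatePairwiseRandomDispersion
#' @return a [CountData-class] object; `rowData$pattern` is one of
#'   `"none"`, `"{A,B}{C}"`, `"{A,C}{B}"`, `"{A}{B,C}"`, `"{A}{B}{C}"`
#'   (matching the names produced by [enumerateModels()]), and
#'   `rowData$direction` holds the per-tuple direction (or the role
#'   allocation `"X1X2X3"` order for the all-different pattern).
#' @export
simulateThreeGroup <- function(nTuples = 10000L, n = 2L, perPattern = 500L,
        b = 8, dispersionShape = 0.85, dispersionScale = 0.5,
        lambda = NULL, lambdaMeanlog = log(3e-5), lambdaSdlog = 2,
        libSizeRange = c(30000, 90000), seed = 1L) {
    stopifnot(n >= 1, perPattern >= 0, 4 * perPattern <= nTuples, b > 1)
    .withSeed(seed, {
        nl <- 3L * n
        conds <- rep(c("A", "B", "C"), each = n)
        l <- round(runif(nl, libSizeRange[1L], libSizeRange[2L]))
        lam <- if (is.null(lambda))
            .rlambda(nTuples, lambdaMeanlog, lambdaSdlog)
        else sample(lambda, nTuples, replace = TRUE)
        ph <- rgamma(nTuples, shape = dispersionShape,
                     scale = dispersionScale)
        pats <- c("{A,B}{C}", "{A,C}{B}", "{A}{B,C}", "{A}{B}{C}")
        pattern <- sample(rep(c(pats, "none"),
                              c(rep(perPattern, 4L), nTuples - 4L * perPattern)))
        direction <- character(nTuples)
        direction[pattern == "none"] <- "0"
        fold <- matrix(1, nTuples, nl)
        # one condition vs the other two
        singleton <- c("{A,B}{C}" = "C", "{A,C}{B}" = "B", "{A}{B,C}" = "A")
        for (p in names(singleton)) {
            rows <- which(pattern == p)
            dir <- sample(c(-1L, 1L), length(rows), replace = TRUE)
            direction[rows] <- as.character(dir)
            isS <- conds == singleton[[p]]
            fold[rows, isS] <- ifelse(dir > 0, b, 1 / b)
            fold[rows, !isS] <- ifelse(dir > 0, 1 / b, b)
        }
        # all three different: roles X1 (lambda*l), X2 (/(2b)), X3 (*2b)
        rows <- which(pattern == "{A}{B}{C}")
        roleFold <- c(1, 1 / (2 * b), 2 * b)
        for (t in rows) {
            perm <- sample(3L)   # role of A, B, C
            direction[t] <- paste(c("X1", "X2", "X3")[perm], collapse = "")
            for (g in 1:3)
                fold[t, conds == c("A", "B", "C")[g]] <- roleFold[perm[g]]
        }
        meanMat <- (lam %o% l) * fold
        cts <- .rnbMatrix(meanMat, ph)
        rownames(cts) <- .tupleIds(nTuples)
        colnames(cts) <- paste0(conds, rep(seq_len(n), times = 3L))
        CountData(cts, conditions = conds, libSizes = l,
                  rowData = S4Vectors::DataFrame(
                      pattern = pattern, lambda = lam, phi = ph,
                      direction = direction))
    })
}
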