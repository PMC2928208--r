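#' False discovery rate curve over a ranked list
#'
#' For each list depth `N`, counts the false positives (tuples whose truth
#' label is not differentially expressed) among the top `N` tuples of the
#' ranking and reports `fdr = fp / N`.
#'
#' @param ranking character vector of tuple ids in ranked order (best
#'   first), e.g. `rankTuples(...)$tuple`.
#' @param truth named logical vector: `TRUE` for truly DE tuples; names must
#'   cover every id in `ranking`.
#' @param depths integer grid of list depths (default `1:3000`, truncated to
#'   the ranking length).
#' @return data.frame of class `"fdrCurve"` with columns `depth`,
#'   `fp_count` and `fdr`.
#' @export
fdrCurve <- function(ranking, truth, depths = seq_len(3000L)) {
    unknown <- setdiff(ranking, names(truth))
    if (length(unknown) > 0L)
        stop("ranking contains unlabeled tuple(s): ",
             paste(head(unknown, 5L), collapse = ", "))
    depths <- depths[depths <= length(ranking)]
    fp <- cumsum(!truth[ranking])
    out <- data.frame(depth = depths, fp_count = unname(fp[depths]),
                      fdr = unname(fp[depths]) / depths)
    class(out) <- c("fdrCurve", "data.frame")
    out
}

#' Empirical ROC curve
#'
#' Standard empirical receiver-operating characteristic by descending
#' score; tied scores are grouped into a single step so the curve is
#' deterministic under any input order. The curve starts at (0, 0) and ends
#' at (1, 1).
#'
#' @param scores numeric vector of per-tuple scores (larger = more likely
#'   DE).
#' @param truth logical vector aligned with `scores`.
#' @return data.frame of class `"rocCurve"` with columns `fpr` and `tpr`.
#' @export
rocCurve <- function(scores, truth) {
    truth <- as.logical(truth)
    if (length(scores) != length(truth))
        stop("'scores' and 'truth' lengths differ")
    nP <- sum(truth); nN <- sum(!truth)
    if (nP == 0L || nN == 0L)
        stop("need at least one DE and one non-DE tuple")
    o <- order(-scores)
    s <- scores[o]; tr <- truth[o]
    grp_end <- c(which(diff(s) != 0), length(s))  # last index of each tie group
    tp <- cumsum(tr)[grp_end]
    fp <- cumsum(!tr)[grp_end]
    out <- data.frame(fpr = c(0, fp / nN), tpr = c(0, tp / nP))
    class(out) <- c("rocCurve", "data.frame")
    out
}

#' Area under an ROC curve
#'
#' Trapezoidal area under a curve produced by [rocCurve()].
#'
#' @param roc a `"rocCurve"` data.frame.
#' @return the AUC, in `[0, 1]`.
#' @export
aucROC <- function(roc) {
    sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

# interpolate a ROC curve onto a fixed FPR grid (piecewise linear)
.rocOnGrid <- function(roc, grid) {
    stats::approx(roc$fpr, roc$tpr, xout = grid, ties = "ordered",
                  rule = 2)$y
}

#' Average FDR or ROC curves across simulation replicates
#'
#' Pointwise mean and Monte-Carlo standard error across replicate curves.
#' FDR curves must share their depth grid; ROC curves are first
#' interpolated onto a common false-positive-rate grid (default 512 points)
#' because each replicate has its own thresholds.
#'
#' @param curves list of `"fdrCurve"` or `"rocCurve"` data.frames (all of
#'   the same kind).
#' @param fprGrid grid used for ROC averaging (default
#'   `seq(0, 1, length.out = 512)`).
#' @return data.frame with the grid column (`depth` or `fpr`), `mean` and
#'   `se`; for FDR curves also `mean_fp` and `se_fp` (false-positive
#'   counts).
#' @export
meanCurves <- function(curves, fprGrid = seq(0, 1, length.out = 512L)) {
    if (length(curves) == 0L) stop("no curves supplied")
    kinds <- vapply(curves, function(x) class(x)[1L], "")
    if (length(unique(kinds)) != 1L)
        stop("curves must all be FDR or all ROC")
    R <- length(curves)
    if (kinds[1L] == "fdrCurve") {
        g <- curves[[1L]]$depth
        for (cv in curves)
            if (!identical(cv$depth, g)) stop("mismatched depth grids")
        fdr <- matrix(vapply(curves, function(cv) cv$fdr,
                             numeric(length(g))), nrow = length(g))
        fp <- matrix(vapply(curves, function(cv) as.numeric(cv$fp_count),
                            numeric(length(g))), nrow = length(g))
        data.frame(depth = g,
                   mean = rowMeans(fdr),
                   se = apply(fdr, 1L, sd) / sqrt(R),
                   mean_fp = rowMeans(fp),
                   se_fp = apply(fp, 1L, sd) / sqrt(R))
    } else if (kinds[1L] == "rocCurve") {
        tpr <- matrix(vapply(curves, .rocOnGrid, grid = fprGrid,
                             numeric(length(fprGrid))),
                      nrow = length(fprGrid))
        data.frame(fpr = fprGrid,
                   mean = rowMeans(tpr),
                   se = apply(tpr, 1L, sd) / sqrt(R))
    } else stop("unrecognised curve class: ", kinds[1L])
}

#' Write a curve (or averaged curve) as TSV
#'
#' @param curve a data.frame from [fdrCurve()], [rocCurve()] or
#'   [meanCurves()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCurve <- function(curve, path) {
    write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

# NB log-likelihood maximised over per-group means at fixed phi
.nbProfileLoglik <- function(u, l, groups, phi) {
    sum(vapply(unique(groups), function(g) {
        ug <- u[groups == g]; lg <- l[groups == g]
        mu <- cpp_nb_mean_mle(as.integer(ug), lg, phi)
        if (mu <= 0) mu <- .MU_FLOOR
        sum(cpp_nb_log_pmf(ug, lg, rep(mu, length(ug)),
                           rep(phi, length(ug))))
    }, 1))
}

#' Poisson-versus-negative-binomial overdispersion test
#'
#' For each tuple, fits (i) a Poisson model with one mean per condition
#' group and library sizes as offsets and (ii) a negative-binomial
#' alternative with the same group means plus a single shared dispersion,
#' and refers twice the log-likelihood ratio to a chi-squared reference with
#' one degree of freedom. Because the dispersion is tested on the boundary
#' of its parameter space, the default reference is the 50:50 mixture of a
#' point mass at zero and a 1-df chi-squared (halving the p-value);
#' `boundaryCorrection = FALSE` gives the plain 1-df tail. A tuple with no
#' overdispersion signal (statistic 0, e.g. within-group-constant counts at
#' equal library sizes) gets p = 1; all-zero tuples get p = 1.
#'
#' @param object a [CountData-class] object.
#' @param tuples optional subset of tuples (default: all).
#' @param boundaryCorrection halve the p-value for the boundary null
#'   (default `TRUE`).
#' @return data.frame with one row per tuple: `tuple`, `meanExpression`
#'   (mean of `u/l`, the normalised expression level), `statistic`,
#'   `pValue` and `logP` (natural log).
#' @export
overdispersionLRT <- function(object, tuples = NULL,
                              boundaryCorrection = TRUE) {
    stopifnot(methods::is(object, "CountData"))
    cts <- counts(object)
    if (!is.null(tuples)) cts <- cts[tuples, , drop = FALSE]
    l <- as.numeric(libSizes(object))
    groups <- as.character(conditions(object))
    ug <- unique(groups)
    res <- t(vapply(seq_len(nrow(cts)), function(t) {
        u <- cts[t, ]
        if (all(u == 0)) return(c(0, 0, 1))
        # Poisson: closed-form group means with library-size offsets
        ll0 <- sum(vapply(ug, function(g) {
            sel <- groups == g
            mu <- sum(u[sel]) / sum(l[sel])
            if (mu <= 0) mu <- .MU_FLOOR
            sum(dpois(u[sel], l[sel] * mu, log = TRUE))
        }, 1))
        # NB: profile over log-dispersion
        opt <- optimize(function(lp) .nbProfileLoglik(u, l, groups, exp(lp)),
                        lower = log(1e-8), upper = log(1e3), maximum = TRUE)
        ll1 <- max(opt$objective, ll0)
        stat <- max(0, 2 * (ll1 - ll0))
        p <- if (stat <= 1e-6) 1
             else if (boundaryCorrection)
                 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
             else pchisq(stat, df = 1, lower.tail = FALSE)
        c(mean(u / l), stat, p)
    }, numeric(3)))
    data.frame(tuple = rownames(cts), meanExpression = res[, 1L],
               statistic = res[, 2L], pValue = res[, 3L],
               logP = log(res[, 3L]))
}
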