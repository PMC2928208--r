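test_that("fdrCurve counts false discoveries by hand", {
    truth <- c(a = TRUE, b = FALSE, c = TRUE)
    fc <- fdrCurve(c("a", "b", "c"), truth, depths = 1:3)
    expect_equal(fc$fdr, c(0, 1 / 2, 1 / 3))
    expect_equal(fc$fp_count, c(0, 1, 1))
    # perfect ranking: zero FDR up to the number of DE tuples
    truth2 <- setNames(rep(c(TRUE, FALSE), c(5, 5)), letters[1:10])
    fc2 <- fdrCurve(letters[1:10], truth2, depths = 1:5)
    expect_equal(fc2$fdr, rep(0, 5))
    expect_error(fdrCurve(c("a", "zz"), truth), "unlabeled")
})

test_that("random rankings give FDR near the non-DE fraction", {
    set.seed(3)
    n <- 10000; nDE <- 1000
    truth <- setNames(sample(rep(c(TRUE, FALSE), c(nDE, n - nDE))),
                      sprintf("t%05d", 1:n))
    fdr200 <- replicate(50, {
        fdrCurve(sample(names(truth)), truth, depths = 200)$fdr
    })
    expect_equal(mean(fdr200), 0.9, tolerance = 0.01)
})

test_that("rocCurve matches a threshold-enumeration oracle", {
    bruteROC <- function(scores, truth) {
        ths <- sort(unique(scores), decreasing = TRUE)
        fpr <- c(0, vapply(ths, function(th)
            sum(scores >= th & !truth) / sum(!truth), 1))
        tpr <- c(0, vapply(ths, function(th)
            sum(scores >= th & truth) / sum(truth), 1))
        list(fpr = fpr, tpr = tpr)
    }
    set.seed(7)
    for (rep in 1:25) {
        n <- sample(4:12, 1)
        # coarse scores force plenty of ties
        scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
        truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
        if (!any(truth) || all(truth)) next
        roc <- rocCurve(scores, truth)
        want <- bruteROC(scores, truth)
        expect_equal(roc$fpr, want$fpr)
        expect_equal(roc$tpr, want$tpr)
    }
})

test_that("ROC endpoints, monotonicity, and degenerate scores", {
    # perfect separation
    roc <- rocCurve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(aucROC(roc), 1)
    expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[nrow(roc)], 1)
    # constant scores: one diagonal step, AUC 1/2
    roc2 <- rocCurve(rep(0.5, 6), rep(c(TRUE, FALSE), 3))
    expect_equal(nrow(roc2), 2)
    expect_equal(aucROC(roc2), 0.5)
    expect_true(all(diff(roc2$fpr) >= 0) && all(diff(roc2$tpr) >= 0))
    expect_error(rocCurve(1:3, c(TRUE, TRUE, TRUE)), "at least one")
})

test_that("meanCurves averages pointwise with Monte-Carlo SE", {
    truth <- setNames(rep(c(TRUE, FALSE), c(100, 300)),
                      sprintf("t%03d", 1:400))
    set.seed(9)
    r1 <- fdrCurve(sample(names(truth)), truth, depths = c(100, 200))
    r2 <- fdrCurve(sample(names(truth)), truth, depths = c(100, 200))
    mc <- meanCurves(list(r1, r2))
    expect_equal(mc$mean_fp, (r1$fp_count + r2$fp_count) / 2)
    expect_equal(mc$se_fp,
                 apply(cbind(r1$fp_count, r2$fp_count), 1, sd) / sqrt(2))
    # identical replicates: SE 0
    mc2 <- meanCurves(list(r1, r1, r1))
    expect_equal(mc2$se_fp, c(0, 0))
    expect_equal(mc2$mean, r1$fdr)
    # permutation invariance in replicate order
    expect_equal(meanCurves(list(r2, r1)), mc)
    r3 <- fdrCurve(sample(names(truth)), truth, depths = c(50, 100))
    expect_error(meanCurves(list(r1, r3)), "mismatched")
    # hand check: fp 10 and 20 at one depth -> mean 15, SE 5
    f1 <- data.frame(depth = 200, fp_count = 10, fdr = 0.05)
    f2 <- data.frame(depth = 200, fp_count = 20, fdr = 0.10)
    class(f1) <- class(f2) <- c("fdrCurve", "data.frame")
    mc3 <- meanCurves(list(f1, f2))
    expect_equal(mc3$mean_fp, 15); expect_equal(mc3$se_fp, 5)
})

test_that("meanCurves SE tracks the sampling distribution", {
    # replicate FDR at fixed depth is Binomial(depth, 0.75)/depth here
    set.seed(11)
    truth <- setNames(rep(c(TRUE, FALSE), c(250, 750)),
                      sprintf("t%04d", 1:1000))
    curves <- lapply(1:100, function(i)
        fdrCurve(sample(names(truth)), truth, depths = 100))
    mc <- meanCurves(curves)
    # analytic sd of one replicate's fdr at depth 100 (hypergeometric)
    p <- 0.75; N <- 1000; K <- 750; nn <- 100
    sdAna <- sqrt(nn * (K / N) * (1 - K / N) * (N - nn) / (N - 1)) / nn
    expect_lt(abs(mc$se - sdAna / sqrt(100)) / (sdAna / sqrt(100)), 0.3)
})

test_that("ROC averaging interpolates onto a common FPR grid", {
    r1 <- rocCurve(c(4, 3, 2, 1), c(TRUE, FALSE, TRUE, FALSE))
    r2 <- rocCurve(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE))
    mc <- meanCurves(list(r1, r2), fprGrid = c(0, 0.5, 1))
    expect_equal(mc$fpr, c(0, 0.5, 1))
    expect_equal(mc$mean[3], 1)
    expect_true(all(mc$se >= 0))
})

test_that("overdispersion LRT: boundary cases and power", {
    # within-group-constant counts at equal library sizes: statistic 0, p 1
    cd <- makeCountData(matrix(c(5L, 5L, 9L, 9L), 1, 4),
                        conditions = c("A", "A", "B", "B"))
    res <- overdispersionLRT(cd)
    expect_equal(res$statistic, 0, tolerance = 1e-6)
    expect_equal(res$pValue, 1)
    # all-zero tuple: p 1
    cd0 <- makeCountData(matrix(0L, 1, 4), conditions = c("A", "A", "B", "B"))
    expect_equal(overdispersionLRT(cd0)$pValue, 1)
    # strongly overdispersed tuples: p very small in the vast majority
    set.seed(13)
    nT <- 200
    l <- c(3e4, 5e4, 4e4, 6e4)
    cts <- matrix(rnbinom(nT * 4, mu = rep(0.005 * l, each = nT), size = 1),
                  nT, 4)
    cdo <- makeCountData(cts, conditions = c("A", "A", "B", "B"),
                         libSizes = l)
    reso <- overdispersionLRT(cdo)
    expect_gt(mean(reso$pValue < 1e-4), 0.9)
    expect_equal(reso$logP, log(reso$pValue))
    expect_equal(reso$meanExpression, rowMeans(sweep(cts, 2, l, "/")))
})

test_that("overdispersion LRT is calibrated on Poisson nulls", {
    set.seed(17)
    nT <- 4000
    l <- c(3e4, 5e4, 4e4, 6e4)
    mu <- 10^runif(nT, -4.5, -2.5)
    cts <- matrix(rpois(nT * 4, rep(mu, 4) * rep(l, each = nT)), nT, 4)
    cd <- makeCountData(cts, conditions = c("A", "A", "B", "B"),
                        libSizes = l)
    res <- overdispersionLRT(cd)
    rate <- mean(res$pValue <= 0.05)
    # type-I error at nominal 5%: at most 5% + 3 binomial SEs
    expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / nT))
    # the boundary-corrected test is conservative, not wildly so
    resU <- overdispersionLRT(cd, boundaryCorrection = FALSE)
    expect_true(all(resU$pValue >= res$pValue - 1e-12))
})
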