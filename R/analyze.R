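# name of the single-set (no differential expression) model, if present
.nullModelName <- function(models) {
    one <- vapply(models, function(m) length(modelSets(m)) == 1L, TRUE)
    if (any(one)) names(models)[which(one)[1L]] else NA_character_
}

.writeManifest <- function(path, params) {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(params))
        writeLines(sprintf("%s\t%s", k,
                           paste(format(params[[k]]), collapse = ",")), con)
    invisible(path)
}

#' Run the full empirical Bayes analysis on a count dataset
#'
#' Composes the pipeline: enumerate (or accept) the candidate models, build
#' the empirical priors for every model from randomly sampled tuples,
#' compute Monte-Carlo marginal likelihoods for all tuples, estimate the
#' model prior probabilities by iterated mean posteriors, and return the
#' per-tuple posterior probabilities of every model. When `outputDir` is
#' given, a posterior TSV (with converged priors in comment lines and a
#' combined any-differential-expression column) and a run manifest with
#' every reproducibility-relevant parameter are written; identical inputs
#' and seeds give byte-identical outputs.
#'
#' @param object a [CountData-class] object.
#' @param models optional list of [ModelDefinition-class]; defaults to all
#'   set-partitions of the condition labels ([enumerateModels()]) minus
#'   `exclude`.
#' @param exclude optional condition-partition exclusions, see
#'   [enumerateModels()].
#' @param priorSampleSize tuples sampled for the empirical prior (default
#'   5000).
#' @param seed integer seed for the prior tuple sample.
#' @param initPriors,priorTol,priorMaxIter controls for
#'   [estimateModelPriors()]; supply `initPriors` with `priorMaxIter = 0`
#'   to use fixed, externally estimated model priors.
#' @param phiMin,phiMax,dispTol,dispMaxIter,muFloor,perSetDispersion
#'   dispersion/prior-construction controls, see [buildPriors()].
#' @param outputDir optional directory for `posteriors.tsv` and
#'   `manifest.tsv`.
#' @return a [PosteriorTable-class]; the combined probability of
#'   differential expression of any type is `combineModels(result,
#'   setdiff(colnames(posteriors(result)), nullModel))`.
#' @examples
#' sim <- simulatePairwiseRandomDispersion(nTuples = 300, seed = 3)
#' pt <- runAnalysis(sim, priorSampleSize = 100, seed = 4)
#' modelPriors(pt)
#' @export
runAnalysis <- function(object, models = NULL, exclude = NULL,
                        priorSampleSize = 5000L, seed = 1L,
                        initPriors = NULL, priorTol = 1e-5,
                        priorMaxIter = 1000L, phiMin = .PHI_MIN,
                        phiMax = .PHI_MAX, dispTol = 1e-4,
                        dispMaxIter = 50L, muFloor = .MU_FLOOR,
                        perSetDispersion = FALSE, outputDir = NULL) {
    stopifnot(methods::is(object, "CountData"))
    if (is.null(models))
        models <- enumerateModels(conditions(object), exclude = exclude)
    if (methods::is(models, "ModelDefinition")) models <- list(models)
    if (is.null(names(models)))
        names(models) <- vapply(models, modelName, "")
    priors <- buildPriors(object, models, sampleSize = priorSampleSize,
                          seed = seed, phiMin = phiMin, phiMax = phiMax,
                          tol = dispTol, maxIter = dispMaxIter,
                          muFloor = muFloor,
                          perSetDispersion = perSetDispersion)
    if (methods::is(priors, "PriorSample")) priors <- list(priors)
    lm <- vapply(seq_along(models), function(j)
        marginalLikelihood(object, models[[j]], priors[[j]]),
        numeric(nrow(object)))
    if (is.null(dim(lm))) lm <- matrix(lm, nrow = 1L)
    colnames(lm) <- names(models)
    rownames(lm) <- rownames(object)
    pt <- estimateModelPriors(lm, initPriors = initPriors, tol = priorTol,
                              maxIter = priorMaxIter)
    if (!is.null(outputDir)) {
        dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
        writePosteriors(pt, file.path(outputDir, "posteriors.tsv"))
        .writeManifest(file.path(outputDir, "manifest.tsv"), list(
            package = "ebPatterns",
            version = as.character(packageVersion("ebPatterns")),
            n_tuples = nrow(object), n_samples = ncol(object),
            conditions = conditions(object),
            replicates = replicateGroups(object),
            models = names(models), prior_sample_size = priorSampleSize,
            seed = seed, prior_tol = priorTol,
            prior_max_iter = priorMaxIter, phi_min = phiMin,
            phi_max = phiMax, disp_tol = dispTol,
            disp_max_iter = dispMaxIter, mu_floor = muFloor,
            per_set_dispersion = perSetDispersion,
            prior_iterations = pt@iterations,
            prior_converged = pt@converged))
    }
    pt
}

#' Write a posterior table as TSV
#'
#' One row per tuple with a posterior column per model; converged model
#' priors appear as `# prior:<model>=<value>` comment lines before the
#' header. Additional combined columns (row sums over model subsets, see
#' [combineModels()]) can be requested; by default, if a single-set model is
#' present, an `any_DE` column sums every other model.
#'
#' @param object a [PosteriorTable-class].
#' @param path output path.
#' @param combined named list of model-name subsets to add as combined
#'   columns, or `NULL` for the `any_DE` default.
#' @param countsEcho optional [CountData-class] whose counts are echoed as
#'   leading columns.
#' @return `path`, invisibly.
#' @export
writePosteriors <- function(object, path, combined = NULL,
                            countsEcho = NULL) {
    stopifnot(methods::is(object, "PosteriorTable"))
    post <- posteriors(object)
    if (is.null(combined)) {
        one <- vapply(colnames(post), function(nm)
            length(gregexpr("\\{", nm)[[1L]]) == 1L &&
                grepl("^\\{", nm), TRUE)
        combined <- if (any(one) && !all(one))
            list(any_DE = colnames(post)[!one]) else list()
    }
    tab <- data.frame(tuple = rownames(post), check.names = FALSE)
    if (!is.null(countsEcho))
        tab <- cbind(tab, as.data.frame(counts(countsEcho)[rownames(post), ,
                                                           drop = FALSE]))
    tab <- cbind(tab, as.data.frame(post, check.names = FALSE))
    for (nm in names(combined))
        tab[[nm]] <- combineModels(object, combined[[nm]])
    con <- file(path, "w")
    on.exit(close(con))
    for (m in colnames(post))
        writeLines(sprintf("# prior:%s=%.10g", m, modelPriors(object)[m]),
                   con)
    write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Simulation benchmark: simulate, analyse, rank, and score replicates
#'
#' Loops `simulate -> runAnalysis -> rank by P(DE) -> FDR/ROC` over seeded
#' replicates of one of the simulation designs, and averages the curves.
#' Rankings use the combined posterior probability of differential
#' expression of any type; for the three-group design, per-pattern rankings
#' (each DE model's own posterior against its own truth labels) are scored
#' as well. Replicate seeds are derived deterministically from `seed`, so
#' re-runs are identical.
#'
#' @param design `"pairwise_random"`, `"fixed_dispersion"` or
#'   `"three_group"`.
#' @param nReplicates number of simulation replicates (default 10).
#' @param seed base integer seed.
#' @param designArgs named list of arguments passed to the simulator (e.g.
#'   `list(n1 = 5, n2 = 5, b = 8)`).
#' @param priorSampleSize tuples sampled for the empirical priors.
#' @param depths FDR depth grid (default `1:3000`).
#' @param summaryDepths depths reported in the false-positive summary table
#'   (default 200).
#' @param outputDir optional directory for per-replicate and mean curve
#'   TSVs, the summary table, and a manifest.
#' @return a list with `fdr` (per-replicate FDR curves), `roc`, `meanFDR`,
#'   `meanROC`, `summary` (mean/SE false positives at `summaryDepths`), and
#'   for the three-group design `perModel` mean FDR curves.
#' @export
runBenchmark <- function(design = c("pairwise_random", "fixed_dispersion",
                                    "three_group"),
                         nReplicates = 10L, seed = 1L, designArgs = list(),
                         priorSampleSize = 5000L,
                         depths = seq_len(3000L), summaryDepths = 200L,
                         outputDir = NULL) {
    design <- match.arg(design)
    simfun <- switch(design,
        pairwise_random = simulatePairwiseRandomDispersion,
        fixed_dispersion = simulateFixedDispersion,
        three_group = simulateThreeGroup)
    fdrs <- list(); rocs <- list(); perModel <- list()
    for (i in seq_len(nReplicates)) {
        simSeed <- seed + 1009L * i
        priorSeed <- simSeed + 499L
        sim <- do.call(simfun, c(designArgs, list(seed = simSeed)))
        pt <- runAnalysis(sim, priorSampleSize = priorSampleSize,
                          seed = priorSeed)
        truthPat <- SummarizedExperiment::rowData(sim)$pattern
        names(truthPat) <- rownames(sim)
        nullName <- .nullModelName(
            enumerateModels(conditions(sim)))
        deProb <- combineModels(pt, setdiff(colnames(posteriors(pt)),
                                            nullName))
        truthDE <- setNames(truthPat != "none", names(truthPat))
        ranking <- rankTuples(deProb)$tuple
        fdrs[[i]] <- fdrCurve(ranking, truthDE, depths = depths)
        rocs[[i]] <- rocCurve(deProb, truthDE[names(deProb)])
        if (design == "three_group") {
            for (m in setdiff(colnames(posteriors(pt)), nullName)) {
                pm <- posteriors(pt)[, m]
                tm <- setNames(truthPat == m, names(truthPat))
                perModel[[m]][[i]] <- fdrCurve(rankTuples(pm)$tuple, tm,
                                               depths = depths)
            }
        }
    }
    meanFDR <- meanCurves(fdrs)
    meanROC <- meanCurves(rocs)
    sel <- match(summaryDepths, meanFDR$depth)
    summary <- data.frame(depth = summaryDepths,
                          mean_fp = meanFDR$mean_fp[sel],
                          se_fp = meanFDR$se_fp[sel],
                          mean_fdr = meanFDR$mean[sel])
    out <- list(fdr = fdrs, roc = rocs, meanFDR = meanFDR,
                meanROC = meanROC, summary = summary)
    if (length(perModel) > 0L)
        out$perModel <- lapply(perModel, meanCurves)
    if (!is.null(outputDir)) {
        dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
        for (i in seq_len(nReplicates)) {
            writeCurve(fdrs[[i]],
                       file.path(outputDir, sprintf("fdr_rep%03d.tsv", i)))
            writeCurve(rocs[[i]],
                       file.path(outputDir, sprintf("roc_rep%03d.tsv", i)))
        }
        writeCurve(meanFDR, file.path(outputDir, "fdr_mean.tsv"))
        writeCurve(meanROC, file.path(outputDir, "roc_mean.tsv"))
        write.table(summary, file.path(outputDir, "summary.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        .writeManifest(file.path(outputDir, "manifest.tsv"), list(
            package = "ebPatterns",
            version = as.character(packageVersion("ebPatterns")),
            design = design, n_replicates = nReplicates, seed = seed,
            design_args = if (length(designArgs))
                paste(names(designArgs), unlist(designArgs), sep = "=")
                else "defaults",
            prior_sample_size = priorSampleSize,
            summary_depths = summaryDepths))
    }
    out
}
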