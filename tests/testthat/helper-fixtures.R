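# small in-code fixtures shared across test files

# a CountData with explicit unit library sizes (so rates equal raw counts)
makeCountData <- function(counts, conditions, libSizes = NULL,
                          replicates = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("t", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("s", seq_len(ncol(counts)))
    if (is.null(libSizes)) libSizes <- rep(1, ncol(counts))
    CountData(counts, conditions = conditions, libSizes = libSizes,
              replicates = replicates)
}

# independent brute-force enumeration of set partitions of 1..k, built by
# inserting element k into every block (or a new block) of each partition
# of 1..k-1 -- a different construction from the package's
bruteForcePartitions <- function(k) {
    if (k == 1) return(list(list(1L)))
    smaller <- bruteForcePartitions(k - 1)
    out <- list()
    for (p in smaller) {
        for (b in seq_along(p)) {
            q <- p
            q[[b]] <- c(q[[b]], k)
            out[[length(out) + 1]] <- q
        }
        out[[length(out) + 1]] <- c(p, list(k))
    }
    out
}

# canonical string form of a partition (for set comparisons)
partitionKey <- function(sets) {
    sets <- lapply(sets, sort)
    sets <- sets[order(vapply(sets, min, 1L))]
    paste(vapply(sets, paste, "", collapse = ","), collapse = "|")
}

# truth labels of a simulated dataset as a named logical (TRUE = DE)
truthDE <- function(sim) {
    pat <- SummarizedExperiment::rowData(sim)$pattern
    stats::setNames(pat != "none", rownames(sim))
}

simPattern <- function(sim) {
    stats::setNames(SummarizedExperiment::rowData(sim)$pattern,
                    rownames(sim))
}
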