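#' Construct a CountData object
#'
#' @param counts integer matrix of non-negative counts, tuples x samples.
#'   Rownames (tuple identifiers) are required to be unique; if absent,
#'   `tuple_1 ... tuple_T` are assigned.
#' @param conditions character or factor of length `ncol(counts)`: the
#'   experimental condition of each sample.
#' @param libSizes optional positive numeric of length `ncol(counts)`;
#'   defaults to the column totals of `counts` (the library size is the
#'   total number of counts in a library, or a user-supplied surrogate).
#' @param replicates optional replicate-group label per sample; samples with
#'   the same label are biological replicates. Defaults to `conditions`.
#'   Used only for dispersion estimation.
#' @param rowData optional `DataFrame` of per-tuple annotation.
#'
#' @return a validated [CountData-class] object.
#' @examples
#' cts <- matrix(rpois(40, 10), 10, 4,
#'               dimnames = list(paste0("t", 1:10), paste0("s", 1:4)))
#' cd <- CountData(cts, conditions = c("A", "A", "B", "B"))
#' libSizes(cd)
#' @export
CountData <- function(counts, conditions, libSizes = NULL, replicates = NULL,
                      rowData = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("tuple_", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
    storage.mode(counts) <- "integer"
    if (length(conditions) != ncol(counts))
        stop("'conditions' must give one label per sample column")
    if (is.null(libSizes)) libSizes <- colSums(counts)
    if (is.null(replicates)) replicates <- conditions
    cdat <- S4Vectors::DataFrame(
        libSize = as.numeric(libSizes),
        condition = as.character(conditions),
        replicate = as.character(replicates),
        row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cdat)
    if (!is.null(rowData))
        SummarizedExperiment::rowData(se) <- rowData
    methods::new("CountData", se)
}

#' @rdname CountData
#' @export
setMethod("counts", "CountData", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' @rdname CountData
#' @export
setMethod("libSizes", "CountData", function(object)
    setNames(SummarizedExperiment::colData(object)$libSize, colnames(object)))

#' @rdname CountData
#' @export
setMethod("conditions", "CountData", function(object)
    setNames(SummarizedExperiment::colData(object)$condition,
             colnames(object)))

#' @rdname CountData
#' @export
setMethod("replicateGroups", "CountData", function(object)
    setNames(SummarizedExperiment::colData(object)$replicate,
             colnames(object)))

setMethod("show", "CountData", function(object) {
    cat(sprintf("CountData: %d tuples x %d samples\n",
                nrow(object), ncol(object)))
    cat("conditions:",
        paste(sprintf("%s(%d)", names(table(conditions(object))),
                      table(conditions(object))), collapse = " "), "\n")
    cat("library sizes:",
        paste(format(libSizes(object), big.mark = ","), collapse = " "), "\n")
    truth <- SummarizedExperiment::rowData(object)$pattern
    if (!is.null(truth))
        cat("truth labels:",
            paste(sprintf("%s(%d)", names(table(truth)), table(truth)),
                  collapse = " "), "\n")
})

# replicate groups as integer codes 1..s plus the group count
.repCodes <- function(cd) {
    f <- factor(replicateGroups(cd))
    list(codes = as.integer(f), n = nlevels(f))
}

#' Read a tuple-by-sample count table from TSV
#'
#' The file must be tab-delimited with a header row of sample names and the
#' tuple identifier in the first column. All count entries must be
#' non-negative integers. Library sizes default to the column totals unless
#' `libSizesFile` (TSV: sample, size) overrides them.
#'
#' @param path path to the counts TSV.
#' @param conditions condition label per sample column (in file order).
#' @param libSizesFile optional path to a two-column TSV of library sizes.
#' @param replicates optional replicate labels, as in [CountData()].
#' @return a [CountData-class] object.
#' @export
readCounts <- function(path, conditions, libSizesFile = NULL,
                       replicates = NULL) {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 3L)
        stop("counts TSV needs an id column plus >= 2 sample columns: ", path)
    ids <- as.character(tab[[1L]])
    if (anyDuplicated(ids)) {
        dup <- ids[duplicated(ids)][1L]
        stop(sprintf("duplicate tuple id '%s' (line %d)", dup,
                     which(ids == dup)[2L] + 1L))
    }
    raw <- as.matrix(tab[, -1L, drop = FALSE])
    num <- suppressWarnings(
        matrix(as.numeric(raw), nrow(raw), dimnames = dimnames(raw)))
    badcell <- which(is.na(num), arr.ind = TRUE)
    if (nrow(badcell) > 0L)
        stop(sprintf("non-numeric or missing count at line %d, column '%s'",
                     badcell[1L, 1L] + 1L, colnames(num)[badcell[1L, 2L]]))
    offint <- which(num != floor(num) | num < 0, arr.ind = TRUE)
    if (nrow(offint) > 0L)
        stop(sprintf(
            "count '%s' at line %d, column '%s' is not a non-negative integer",
            format(num[offint[1L, , drop = FALSE]]), offint[1L, 1L] + 1L,
            colnames(num)[offint[1L, 2L]]))
    rownames(num) <- ids
    libSizes <- NULL
    if (!is.null(libSizesFile)) {
        lstab <- read.delim(libSizesFile, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
        # accept an optional header row
        if (!is.numeric(lstab[[2L]]) &&
            is.na(suppressWarnings(as.numeric(lstab[1L, 2L]))))
            lstab <- lstab[-1L, , drop = FALSE]
        sizes <- setNames(as.numeric(lstab[[2L]]), as.character(lstab[[1L]]))
        missing <- setdiff(colnames(num), names(sizes))
        if (length(missing) > 0L)
            stop("library-size file lacks sample(s): ",
                 paste(missing, collapse = ", "))
        libSizes <- sizes[colnames(num)]
    }
    CountData(num, conditions = conditions, libSizes = libSizes,
              replicates = replicates)
}

#' Write a CountData object as TSV
#'
#' Inverse of [readCounts()]: a tab-delimited table with tuple ids in the
#' first column (`tuple`) and one column per sample. If the object carries
#' truth labels (from a simulator), these can be written alongside with
#' [writeTruth()].
#'
#' @param object a [CountData-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(object, path) {
    tab <- data.frame(tuple = rownames(object), counts(object),
                      check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCounts
#' @details `writeTruth` writes the per-tuple simulation ground truth
#'   (pattern label, expression rate lambda, dispersion phi, direction) as a
#'   TSV; it errors if the object does not come from one of the simulators.
#' @export
writeTruth <- function(object, path) {
    rd <- SummarizedExperiment::rowData(object)
    if (is.null(rd$pattern))
        stop("object carries no truth labels (not a simulated dataset?)")
    tab <- data.frame(tuple = rownames(object), pattern = rd$pattern,
                      lambda = rd$lambda, phi = rd$phi,
                      direction = rd$direction, check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
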