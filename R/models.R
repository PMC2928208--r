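#' Define a model: a partition of samples into equivalence sets
#'
#' A model asserts that samples within the same set share identical
#' underlying negative-binomial parameters for every tuple, while samples
#' in different sets may differ. The sets must be pairwise disjoint,
#' non-empty, and cover every sample.
#'
#' @param sets list of integer vectors of sample indices.
#' @param name optional label; defaults to a canonical `{i,j}{k,...}` string.
#' @return a [ModelDefinition-class] object in canonical form (members
#'   ascending within sets, sets ordered by smallest member).
#' @examples
#' ModelDefinition(list(c(1, 2), c(3, 4)))      # pairwise DE for 2+2 samples
#' ModelDefinition(list(1:4), name = "no-DE")
#' @export
ModelDefinition <- function(sets, name = NULL) {
    sets <- lapply(sets, function(s) sort(as.integer(s)))
    sets <- sets[order(vapply(sets, min, 1L))]
    if (is.null(name))
        name <- paste0(vapply(sets, function(s)
            paste0("{", paste(s, collapse = ","), "}"), ""), collapse = "")
    methods::new("ModelDefinition", name = name, sets = sets)
}

#' @rdname ModelDefinition-class
#' @export
setMethod("modelName", "ModelDefinition", function(object) object@name)

#' @rdname ModelDefinition-class
#' @export
setMethod("modelSets", "ModelDefinition", function(object) object@sets)

setMethod("show", "ModelDefinition", function(object) {
    cat(sprintf("ModelDefinition '%s': %d set(s)\n", object@name,
                length(object@sets)))
    for (s in object@sets)
        cat("  {", paste(s, collapse = ", "), "}\n")
})

#' Validate a model against the number of samples
#'
#' Checks that the sets of a model form a partition of `1:nSamples` (pairwise
#' disjoint, non-empty, jointly exhaustive) and returns the model in
#' canonical ordering for deterministic downstream iteration.
#'
#' @param model a [ModelDefinition-class] object.
#' @param nSamples the number of samples in the experiment.
#' @return the validated, canonicalized model.
#' @examples
#' validateModel(ModelDefinition(list(c(1, 2), c(3, 4))), 4)
#' @export
validateModel <- function(model, nSamples) {
    stopifnot(methods::is(model, "ModelDefinition"))
    sets <- modelSets(model)
    for (k in seq_along(sets)) {
        s <- sets[[k]]
        if (length(s) == 0L)
            stop(sprintf("model '%s': set %d is empty", modelName(model), k))
        if (any(s < 1L) || any(s > nSamples))
            stop(sprintf(
                "model '%s': set {%s} contains indices outside 1..%d",
                modelName(model), paste(s, collapse = ","), nSamples))
        if (anyDuplicated(s))
            stop(sprintf("model '%s': set {%s} has repeated samples",
                         modelName(model), paste(s, collapse = ",")))
    }
    all_idx <- unlist(sets)
    dup <- all_idx[duplicated(all_idx)]
    if (length(dup) > 0L) {
        off <- which(vapply(sets, function(s) dup[1L] %in% s, TRUE))
        stop(sprintf(
            "model '%s': sample %d appears in more than one set (sets %s)",
            modelName(model), dup[1L], paste(off, collapse = " and ")))
    }
    missing <- setdiff(seq_len(nSamples), all_idx)
    if (length(missing) > 0L)
        stop(sprintf("model '%s': sample(s) %s not assigned to any set",
                     modelName(model), paste(missing, collapse = ", ")))
    ModelDefinition(sets, name = modelName(model))
}

# all set partitions of 1..k as lists of integer vectors (restricted-growth
# strings, lexicographic); k <= ~10 is practical
.setPartitions <- function(k) {
    if (k == 0L) return(list())
    out <- list()
    recurse <- function(assign, nblocks) {
        i <- length(assign) + 1L
        if (i > k) {
            blocks <- split(seq_len(k), assign)
            out[[length(out) + 1L]] <<- unname(blocks)
            return(invisible())
        }
        for (b in seq_len(nblocks + 1L))
            recurse(c(assign, b), max(nblocks, b))
    }
    recurse(integer(0), 0L)
    out
}

# canonical name for a partition of condition labels, ordering conditions
# within blocks and blocks themselves by first appearance in `levels`
.partitionName <- function(blocks, levels) {
    blocks <- lapply(blocks, function(b) b[order(match(b, levels))])
    blocks <- blocks[order(vapply(blocks, function(b) match(b[1L], levels), 1L))]
    paste0(vapply(blocks, function(b)
        paste0("{", paste(b, collapse = ","), "}"), ""), collapse = "")
}

#' Enumerate all candidate models for a set of conditions
#'
#' Generates one model per set-partition of the distinct condition labels:
#' samples are grouped by condition, and each partition of conditions into
#' blocks yields the model whose sets are the unions of samples of the
#' conditions in each block. The number of partitions of `k` conditions is
#' the Bell number `B(k)` (2 conditions give 2 models; 3 give 5; 4 give 15).
#' Models can be excluded on biological grounds by listing the corresponding
#' condition partitions (for instance, when one condition is a known subtype
#' of another, the model separating it alone may be implausible).
#'
#' @param conditionLabels character vector: one condition label per sample.
#' @param exclude optional list of partitions of the condition labels (each
#'   a list of character vectors) to drop from the enumeration.
#' @return a list of validated [ModelDefinition-class] objects, named by
#'   their condition partition (e.g. `"{A,B}{C}"`).
#' @examples
#' names(enumerateModels(c("A", "A", "B", "B", "C", "C")))  # 5 models
#' @export
enumerateModels <- function(conditionLabels, exclude = NULL) {
    conditionLabels <- as.character(conditionLabels)
    levels <- unique(conditionLabels)
    k <- length(levels)
    if (k < 1L) stop("at least one condition label is required")
    parts <- .setPartitions(k)
    excl_names <- character(0)
    if (!is.null(exclude)) {
        for (ex in exclude) {
            labs <- unlist(ex)
            unknown <- setdiff(labs, levels)
            if (length(unknown) > 0L)
                stop("exclusion references unknown condition(s): ",
                     paste(unknown, collapse = ", "))
            if (!setequal(labs, levels) || anyDuplicated(labs))
                stop("an exclusion must be a partition of all conditions")
            excl_names <- c(excl_names,
                            .partitionName(lapply(ex, as.character), levels))
        }
    }
    out <- list()
    for (p in parts) {
        blocks <- lapply(p, function(ix) levels[ix])
        nm <- .partitionName(blocks, levels)
        if (nm %in% excl_names) next
        sets <- lapply(blocks, function(b)
            which(conditionLabels %in% b))
        out[[nm]] <- validateModel(ModelDefinition(sets, name = nm),
                                   length(conditionLabels))
    }
    out
}
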