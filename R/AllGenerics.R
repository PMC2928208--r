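#' @rdname CountData
#' @param object,x a `CountData`, `PriorSample` or `PosteriorTable` object.
#' @export
setGeneric("libSizes", function(object) standardGeneric("libSizes"))

#' @rdname CountData
#' @export
setGeneric("conditions", function(object) standardGeneric("conditions"))

#' @rdname CountData
#' @export
setGeneric("replicateGroups",
    function(object) standardGeneric("replicateGroups"))

#' @rdname ModelDefinition-class
#' @param object a `ModelDefinition`.
#' @export
setGeneric("modelName", function(object) standardGeneric("modelName"))

#' @rdname ModelDefinition-class
#' @export
setGeneric("modelSets", function(object) standardGeneric("modelSets"))

#' @rdname PosteriorTable-class
#' @param object a `PosteriorTable`.
#' @export
setGeneric("posteriors", function(object) standardGeneric("posteriors"))

#' @rdname PosteriorTable-class
#' @export
setGeneric("modelPriors", function(object) standardGeneric("modelPriors"))

#' @rdname PosteriorTable-class
#' @export
setGeneric("logMarginals", function(object) standardGeneric("logMarginals"))

#' @rdname PosteriorTable-class
#' @export
setGeneric("priorHistory", function(object) standardGeneric("priorHistory"))
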