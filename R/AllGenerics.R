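#' @rdname classifyPatterns
#' @export
setGeneric("classifyPatterns", function(x, thresholds = patternThresholds(), ...)
  standardGeneric("classifyPatterns"))

#' @rdname spmMatrix
#' @export
setGeneric("spmMatrix", function(x, ...) standardGeneric("spmMatrix"))

#' @rdname PatternCallSet-accessors
#' @export
setGeneric("patternCalls", function(object) standardGeneric("patternCalls"))

#' @rdname PatternCallSet-accessors
#' @export
setGeneric("skippedGenes", function(object) standardGeneric("skippedGenes"))

#' @rdname PatternCallSet-accessors
#' @export
setGeneric("thresholds", function(object) standardGeneric("thresholds"))

#' @rdname PatternCallSet-accessors
#' @export
setGeneric("datasetId", function(object) standardGeneric("datasetId"))
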