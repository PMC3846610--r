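#' Accessors for PatternCallSet objects
#'
#' @param object A [PatternCallSet-class].
#' @return `patternCalls` returns the call DataFrame, `skippedGenes` the
#'   skip-log DataFrame, `thresholds` the [PatternThresholds-class] used and
#'   `datasetId` the dataset label.
#' @aliases patternCalls,PatternCallSet-method
#'   skippedGenes,PatternCallSet-method thresholds,PatternCallSet-method
#'   datasetId,PatternCallSet-method length,PatternCallSet-method
#' @name PatternCallSet-accessors
NULL

#' @rdname PatternCallSet-accessors
#' @export
setMethod("patternCalls", "PatternCallSet", function(object) object@calls)

#' @rdname PatternCallSet-accessors
#' @export
setMethod("skippedGenes", "PatternCallSet", function(object) object@skipped)

#' @rdname PatternCallSet-accessors
#' @export
setMethod("thresholds", "PatternCallSet", function(object) object@thresholds)

#' @rdname PatternCallSet-accessors
#' @export
setMethod("datasetId", "PatternCallSet", function(object) object@datasetId)

#' @rdname PatternCallSet-accessors
#' @export
setMethod("length", "PatternCallSet", function(x) nrow(x@calls))

setMethod("show", "PatternCallSet", function(object) {
  counts <- table(object@calls$pattern)
  cat("PatternCallSet for dataset '", object@datasetId, "'\n", sep = "")
  cat("  ", nrow(object@calls), " call(s) over ",
      length(unique(object@calls$gene)), " gene(s): ",
      paste(sprintf("%s %d", names(counts), as.integer(counts)),
            collapse = ", "), "\n", sep = "")
  if (nrow(object@skipped)) {
    cat("  ", nrow(object@skipped), " skipped gene record(s)\n", sep = "")
  }
})

#' Flatten a PatternCallSet to a base data.frame
#'
#' List columns (supporting samples and their SPM values) are collapsed to
#' comma-separated strings; this is the layout [writePatternReport()] uses
#' for its TSV dialect.
#'
#' @param x A [PatternCallSet-class].
#' @param row.names,optional,... Ignored (base generic signature).
#' @return A data.frame with one row per call.
#' @export
as.data.frame.PatternCallSet <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  calls <- x@calls
  data.frame(
    gene = calls$gene,
    pattern = as.character(calls$pattern),
    dataset = rep(x@datasetId, nrow(calls)),
    k = calls$k,
    samples = vapply(calls$samples, paste, character(1), collapse = ","),
    spm = vapply(calls$spm, function(v)
      paste(formatC(v, digits = 2, format = "f"), collapse = ","),
      character(1)),
    dpm = calls$dpm, ctm = calls$ctm, rpm = calls$rpm,
    stringsAsFactors = FALSE)
}
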