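#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Classification thresholds for the four pattern-gene classes
#'
#' Holds the cut-offs applied by [classifyPatterns()].  The defaults are the
#' quick-search criteria used for pattern-gene retrieval: SPM > 0.9 for
#' specific genes; DPM < 0.3 for housekeeping genes; k in 2..6 samples, each
#' SPM > 0.3 and CTM > 0.9 for selective genes; k in 1..6 samples, each
#' SPM < 0.1 and RPM < 0.2 for repressed genes.  All comparisons are strict
#' inequalities: a statistic exactly equal to its threshold produces no call.
#'
#' @slot specificSpmMin SPM a sample must exceed for a specific call (0.9).
#' @slot housekeepingDpmMax DPM a gene must stay below for a housekeeping
#'   call (0.3).
#' @slot selectiveKMin,selectiveKMax Range of subset sizes tried for
#'   selective calls (2, 6).
#' @slot selectiveSpmMin Per-sample SPM each of the top-k samples must
#'   exceed (0.3).
#' @slot selectiveCtmMin CTM the top-k subset must exceed (0.9).
#' @slot repressedKMin,repressedKMax Range of subset sizes tried for
#'   repressed calls (1, 6).
#' @slot repressedSpmMax Per-sample SPM each of the bottom-k samples must
#'   stay below (0.1).
#' @slot repressedRpmMax RPM the bottom-k split must stay below (0.2).
#' @seealso [patternThresholds()] for the user constructor.
#' @export
setClass("PatternThresholds",
  slots = c(
    specificSpmMin     = "numeric",
    housekeepingDpmMax = "numeric",
    selectiveKMin      = "integer",
    selectiveKMax      = "integer",
    selectiveSpmMin    = "numeric",
    selectiveCtmMin    = "numeric",
    repressedKMin      = "integer",
    repressedKMax      = "integer",
    repressedSpmMax    = "numeric",
    repressedRpmMax    = "numeric"
  ),
  prototype = list(
    specificSpmMin     = 0.9,
    housekeepingDpmMax = 0.3,
    selectiveKMin      = 2L,
    selectiveKMax      = 6L,
    selectiveSpmMin    = 0.3,
    selectiveCtmMin    = 0.9,
    repressedKMin      = 1L,
    repressedKMax      = 6L,
    repressedSpmMax    = 0.1,
    repressedRpmMax    = 0.2
  )
)

setValidity("PatternThresholds", function(object) {
  msgs <- character()
  real <- c(specificSpmMin = object@specificSpmMin,
            housekeepingDpmMax = object@housekeepingDpmMax,
            selectiveSpmMin = object@selectiveSpmMin,
            selectiveCtmMin = object@selectiveCtmMin,
            repressedSpmMax = object@repressedSpmMax,
            repressedRpmMax = object@repressedRpmMax)
  bad <- names(real)[is.na(real) | real < 0 | real > 1]
  if (length(bad)) {
    msgs <- c(msgs, paste0("threshold(s) outside [0, 1]: ",
                           paste(bad, collapse = ", ")))
  }
  if (length(object@selectiveKMin) != 1L || length(object@selectiveKMax) != 1L ||
      is.na(object@selectiveKMin) || is.na(object@selectiveKMax) ||
      object@selectiveKMin < 1L || object@selectiveKMin > object@selectiveKMax) {
    msgs <- c(msgs, "selective k bounds must satisfy 1 <= kMin <= kMax")
  }
  if (length(object@repressedKMin) != 1L || length(object@repressedKMax) != 1L ||
      is.na(object@repressedKMin) || is.na(object@repressedKMax) ||
      object@repressedKMin < 1L || object@repressedKMin > object@repressedKMax) {
    msgs <- c(msgs, "repressed k bounds must satisfy 1 <= kMin <= kMax")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PatternThresholds object
#'
#' @param specificSpmMin,housekeepingDpmMax,selectiveKMin,selectiveKMax,selectiveSpmMin,selectiveCtmMin,repressedKMin,repressedKMax,repressedSpmMax,repressedRpmMax
#'   See the slot documentation of [PatternThresholds-class]; defaults are
#'   the quick-search criteria.
#' @return A validated [PatternThresholds-class] object.
#' @examples
#' patternThresholds()                       # the defaults
#' patternThresholds(specificSpmMin = 0.95)  # stricter specific calls
#' @export
patternThresholds <- function(specificSpmMin = 0.9,
                              housekeepingDpmMax = 0.3,
                              selectiveKMin = 2L,
                              selectiveKMax = 6L,
                              selectiveSpmMin = 0.3,
                              selectiveCtmMin = 0.9,
                              repressedKMin = 1L,
                              repressedKMax = 6L,
                              repressedSpmMax = 0.1,
                              repressedRpmMax = 0.2) {
  new("PatternThresholds",
      specificSpmMin = as.numeric(specificSpmMin),
      housekeepingDpmMax = as.numeric(housekeepingDpmMax),
      selectiveKMin = as.integer(selectiveKMin),
      selectiveKMax = as.integer(selectiveKMax),
      selectiveSpmMin = as.numeric(selectiveSpmMin),
      selectiveCtmMin = as.numeric(selectiveCtmMin),
      repressedKMin = as.integer(repressedKMin),
      repressedKMax = as.integer(repressedKMax),
      repressedSpmMax = as.numeric(repressedSpmMax),
      repressedRpmMax = as.numeric(repressedRpmMax))
}

.patternClassLevels <- c("specific", "selective", "housekeeping", "repressed")

#' Set of pattern-gene calls for one dataset
#'
#' Returned by [classifyPatterns()].  The call table (one row per call; a
#' gene may carry several calls, one per qualifying class) is available via
#' [patternCalls()]; genes that could not be evaluated (all-zero profile,
#' missing values, repression measure undefined for every candidate k) are
#' recorded with a reason in [skippedGenes()].
#'
#' @slot calls A [S4Vectors::DataFrame] with columns `gene`, `pattern`
#'   (factor: specific, selective, housekeeping, repressed), `k` (subset
#'   size; 1 for specific, n for housekeeping), `samples`
#'   ([IRanges::CharacterList] of the samples supporting the call), `spm`
#'   ([IRanges::NumericList] of those samples' SPM values), and the tested
#'   statistics `dpm`, `ctm`, `rpm` (NA where the class's rule does not use
#'   them).
#' @slot skipped A DataFrame with columns `gene`, `class` (the class whose
#'   evaluation was abandoned, or "all" for profile-level problems) and
#'   `reason`.
#' @slot thresholds The [PatternThresholds-class] used.
#' @slot datasetId Dataset label stamped on every call.
#' @export
setClass("PatternCallSet",
  slots = c(
    calls      = "DataFrame",
    skipped    = "DataFrame",
    thresholds = "PatternThresholds",
    datasetId  = "character"
  )
)

setValidity("PatternCallSet", function(object) {
  needed <- c("gene", "pattern", "k", "samples", "spm", "dpm", "ctm", "rpm")
  if (!all(needed %in% colnames(object@calls))) {
    return(paste0("calls must have columns: ", paste(needed, collapse = ", ")))
  }
  if (!identical(levels(object@calls$pattern), .patternClassLevels)) {
    return("pattern must be a factor with levels specific, selective, housekeeping, repressed")
  }
  if (any(lengths(object@calls$samples) == 0L)) {
    return("every call must name at least one supporting sample")
  }
  TRUE
})
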