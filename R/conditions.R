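# Condition constructors shared across the package.
#
# Two error families are distinguished so callers can react differently:
#   - validation errors: the input violates a structural precondition
#     (negative values, bad indices, shape mismatches);
#   - undefined-statistic errors: the input is structurally fine but the
#     statistic has no value (all-zero profile, zero in the RPM expression
#     group).  Matrix-level drivers catch these and skip the gene with a
#     log record instead of aborting the run.

.stopValidation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("patternGenesValidationError",
                                "patternGenesError")))
}

.stopUndefined <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("patternGenesUndefinedStatistic",
                                "patternGenesError")))
}

#' @keywords internal
.checkProfile <- function(x, clampNegatives = FALSE, what = "profile") {
  if (!is.numeric(x)) {
    .stopValidation("%s must be numeric, got %s", what, class(x)[1L])
  }
  if (length(x) < 2L) {
    .stopValidation("%s must contain at least 2 samples, got %d",
                    what, length(x))
  }
  if (anyNA(x)) {
    .stopValidation("%s contains %d missing value(s); resolve missing cells before computing statistics",
                    what, sum(is.na(x)))
  }
  if (any(x < 0)) {
    if (clampNegatives) {
      x[x < 0] <- 0
    } else {
      .stopValidation("%s contains negative values (min %.4g); expression statistics assume nonnegative intensities (use clampNegatives = TRUE to floor them at 0)",
                      what, min(x))
    }
  }
  if (all(x == 0)) {
    .stopUndefined("%s is all-zero: specificity statistics are undefined", what)
  }
  x
}

.checkSubset <- function(subset, n, allowFull = TRUE, what = "subset") {
  if (length(subset) == 0L) {
    .stopValidation("%s must contain at least one sample index", what)
  }
  if (anyNA(subset) || !is.numeric(subset) || any(subset != as.integer(subset))) {
    .stopValidation("%s must be whole-number sample indices", what)
  }
  subset <- as.integer(subset)
  if (anyDuplicated(subset)) {
    .stopValidation("%s contains duplicated indices", what)
  }
  if (any(subset < 1L) || any(subset > n)) {
    .stopValidation("%s indices must lie in [1, %d] (1-based)", what, n)
  }
  if (!allowFull && length(subset) >= n) {
    .stopValidation("%s must be a proper subset of the %d samples", what, n)
  }
  subset
}
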