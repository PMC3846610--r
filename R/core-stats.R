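#' Specificity measure (SPM) of an expression profile at one sample
#'
#' The SPM of sample \eqn{i} is the cosine of the angle between the full
#' expression vector \eqn{X = (x_1, \dots, x_n)} and its one-sample
#' projection \eqn{X_i} (the vector equal to \eqn{X} at position \eqn{i} and
#' zero elsewhere):
#' \deqn{SPM_i = \cos\theta = \frac{X_i \cdot X}{|X_i||X|} = \frac{x_i}{\sqrt{\sum_j x_j^2}}.}
#' SPM ranges from 0 to 1; 1 means the gene is expressed in sample \eqn{i}
#' only, \eqn{1/\sqrt{n}} means perfectly uniform expression.  Across all
#' samples the squared SPM values sum to one, so at most one sample can have
#' SPM above \eqn{\sqrt{0.5}}.
#'
#' @param x Numeric vector of nonnegative expression values, length >= 2.
#' @param i Sample index (1-based).
#' @param clampNegatives Floor negative values at zero instead of erroring.
#' @return A number in \[0, 1\].
#' @seealso [spmProfile()], [dpm()], [ctm()], [rpm()], [expressionFraction()]
#' @examples
#' spm(c(0, 0, 5, 0), 3)  # 1: expressed in a single sample
#' spm(c(1, 1, 1, 1), 2)  # 0.5: uniform on n = 4 gives 1/sqrt(n)
#' @export
spm <- function(x, i, clampNegatives = FALSE) {
  x <- .checkProfile(x, clampNegatives)
  i <- .checkSubset(i, length(x), what = "sample index")
  if (length(i) != 1L) {
    .stopValidation("spm() takes a single sample index; use spmProfile() for all samples")
  }
  unname(x[i] / sqrt(sum(x^2)))
}

#' SPM profile of a gene
#'
#' Maps an expression profile onto the unit sphere: element \eqn{i} is
#' [spm()] of sample \eqn{i}.  For any profile with a positive value the
#' squared elements sum to exactly 1.
#'
#' @inheritParams spm
#' @return Numeric vector of SPM values, same length and names as `x`.
#' @export
spmProfile <- function(x, clampNegatives = FALSE) {
  x <- .checkProfile(x, clampNegatives)
  x / sqrt(sum(x^2))
}

#' Dispersion measure (DPM) of an expression profile
#'
#' DPM is the standard deviation of the SPM profile rescaled to the unit
#' interval: \deqn{DPM = s(X_{SPM}) \sqrt{n},} where \eqn{s} is the sample
#' standard deviation (divisor \eqn{n - 1}).  The \eqn{\sqrt{n}} factor is
#' the unique affine scaling for which a perfectly uniform profile scores 0
#' and a single-sample spike scores exactly 1, making profiles of different
#' lengths and absolute levels comparable.  Low DPM identifies
#' housekeeping-like (near-uniform) expression.
#'
#' @inheritParams spm
#' @return A number in \[0, 1\].
#' @examples
#' dpm(c(5, 5, 5, 5))   # 0: uniform
#' dpm(c(0, 0, 9, 0))   # 1: single-sample spike
#' dpm(c(3, 4))         # 0.2
#' @export
dpm <- function(x, clampNegatives = FALSE) {
  s <- spmProfile(x, clampNegatives)
  stats::sd(s) * sqrt(length(s))
}

#' Contribution measure (CTM) of a sample subset
#'
#' CTM extends SPM from one sample to a set of \eqn{k} samples: it is the
#' cosine between the projection of the expression vector onto the subset
#' and the full vector,
#' \deqn{CTM = \sqrt{\sum_{i \in subset} SPM_i^2} = \frac{\|X_{subset}\|_2}{\|X\|_2}.}
#' CTM of a singleton reduces to that sample's SPM; CTM over all samples is
#' 1; adding samples never decreases it.  High CTM over a small subset
#' identifies selective (multi-sample enriched) expression.
#'
#' @inheritParams spm
#' @param subset Integer vector of distinct sample indices (1-based).
#' @return A number in \[0, 1\].
#' @examples
#' ctm(c(5, 5, 0, 0, 0), subset = c(1, 2))  # 1: all mass in the subset
#' @export
ctm <- function(x, subset, clampNegatives = FALSE) {
  s <- spmProfile(x, clampNegatives)
  subset <- .checkSubset(subset, length(s))
  ctmFromSpm(s[subset])
}

#' CTM from already-computed SPM components
#'
#' Computes \eqn{\sqrt{\sum SPM_i^2}} for the SPM values of a sample subset.
#' Useful when SPM values are known (e.g. quoted to two decimals) without
#' the underlying raw profile; rounding of the inputs can push the result
#' marginally above 1.
#'
#' @param spmValues Numeric vector of SPM values for the subset.
#' @return The subset's contribution measure.
#' @examples
#' ctmFromSpm(c(0.66, 0.47, 0.59))  # ~1.0
#' @export
ctmFromSpm <- function(spmValues) {
  if (!is.numeric(spmValues) || length(spmValues) == 0L) {
    .stopValidation("spmValues must be a nonempty numeric vector")
  }
  if (anyNA(spmValues) || any(spmValues < 0)) {
    .stopValidation("spmValues must be nonnegative and non-missing")
  }
  sqrt(sum(spmValues^2))
}

#' Repression measure (RPM) of a putative repressed sample group
#'
#' The profile is split into a putative repressed group (normally the
#' \eqn{k} lowest-expression samples) and the remaining expression group.
#' \deqn{RPM = \frac{SPMrep_{max}}{SPMexp_{min}},}
#' the ratio of the largest SPM inside the repressed group to the smallest
#' SPM outside it.  When the repressed group holds the k lowest expressions
#' RPM lies in \[0, 1\]; values near 0 indicate expression in the candidate
#' samples far below every other sample.  RPM is undefined when the
#' expression group contains a zero (the gene is then not "expressed
#' everywhere else"); this raises an undefined-statistic error.
#'
#' @inheritParams ctm
#' @param repressed Integer vector of candidate repressed sample indices
#'   (1-based); must be a proper subset of the samples, and should be the
#'   lowest-expression samples (a warning is issued otherwise).
#' @return A nonnegative number; in \[0, 1\] when `repressed` holds the
#'   lowest expressions.
#' @examples
#' rpm(c(0, 0, 5, 7), repressed = c(1, 2))  # 0: exact repression
#' rpm(c(1, 10, 10, 10), repressed = 1)     # 0.1
#' @export
rpm <- function(x, repressed, clampNegatives = FALSE) {
  s <- spmProfile(x, clampNegatives)
  repressed <- .checkSubset(repressed, length(s), allowFull = FALSE,
                            what = "repressed group")
  expressed <- setdiff(seq_along(s), repressed)
  # stable lowest-k: ties broken by original column order
  lowestK <- order(s, seq_along(s))[seq_along(repressed)]
  if (!setequal(repressed, lowestK) && max(s[repressed]) > min(s[expressed])) {
    warning("repressed group is not the ", length(repressed),
            " lowest-expression sample(s); RPM may exceed 1",
            call. = FALSE)
  }
  spmExpMin <- min(s[expressed])
  if (spmExpMin == 0) {
    .stopUndefined("RPM undefined: the expression group contains a zero-expression sample")
  }
  max(s[repressed]) / spmExpMin
}

#' Fractional expression (proportion baseline)
#'
#' The conventional proportion statistic SPM is compared against:
#' \eqn{r_i = x_i / \sum_j x_j}, the share of the profile's total expression
#' found in sample \eqn{i}.  The fractions sum to 1 and satisfy
#' \eqn{r_i \le SPM_i} for every sample (the L2 norm never exceeds the L1
#' norm), which is why SPM is the more sensitive detector of specific and
#' selective expression.
#'
#' @inheritParams spm
#' @return A number in \[0, 1\].
#' @export
expressionFraction <- function(x, i, clampNegatives = FALSE) {
  x <- .checkProfile(x, clampNegatives)
  i <- .checkSubset(i, length(x), what = "sample index")
  if (length(i) != 1L) {
    .stopValidation("expressionFraction() takes a single sample index")
  }
  unname(x[i] / sum(x))
}

#' Summed fractional expression of a sample subset (SUM baseline)
#'
#' \eqn{SUM = \sum_{i \in subset} r_i}: the share of total expression
#' carried by the subset.  Equals 1 on the full sample set.  This is the
#' proportion-method counterpart of [ctm()].
#'
#' @inheritParams ctm
#' @return A number in \[0, 1\].
#' @export
fractionSum <- function(x, subset, clampNegatives = FALSE) {
  x <- .checkProfile(x, clampNegatives)
  subset <- .checkSubset(subset, length(x))
  sum(x[subset]) / sum(x)
}
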