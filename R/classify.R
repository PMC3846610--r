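# Pattern classification.
#
# The four class rules are evaluated independently per gene (no precedence):
# a gene may legitimately carry several calls, and the table lists them all.
# All threshold comparisons are strict (> / <), so a statistic exactly equal
# to its threshold never produces a call.

.newCallRecord <- function(gene, pattern, k, samples, spmValues,
                           dpm = NA_real_, ctm = NA_real_, rpm = NA_real_) {
  list(gene = gene, pattern = pattern, k = as.integer(k),
       samples = unname(samples), spm = unname(spmValues),
       dpm = unname(dpm), ctm = unname(ctm), rpm = unname(rpm))
}

.recordsToDataFrame <- function(records) {
  if (length(records) == 0L) {
    return(DataFrame(
      gene = character(),
      pattern = factor(character(), levels = .patternClassLevels),
      k = integer(),
      samples = IRanges::CharacterList(),
      spm = IRanges::NumericList(),
      dpm = numeric(), ctm = numeric(), rpm = numeric()))
  }
  DataFrame(
    gene = vapply(records, `[[`, character(1), "gene"),
    pattern = factor(vapply(records, `[[`, character(1), "pattern"),
                     levels = .patternClassLevels),
    k = vapply(records, `[[`, integer(1), "k"),
    samples = IRanges::CharacterList(lapply(records, `[[`, "samples")),
    spm = IRanges::NumericList(lapply(records, `[[`, "spm")),
    dpm = vapply(records, `[[`, numeric(1), "dpm"),
    ctm = vapply(records, `[[`, numeric(1), "ctm"),
    rpm = vapply(records, `[[`, numeric(1), "rpm"))
}

.skipsToDataFrame <- function(skips) {
  if (length(skips) == 0L) {
    return(DataFrame(gene = character(), class = character(),
                     reason = character()))
  }
  DataFrame(
    gene = vapply(skips, `[[`, character(1), "gene"),
    class = vapply(skips, `[[`, character(1), "class"),
    reason = vapply(skips, `[[`, character(1), "reason"))
}

# Evaluate one gene against all four rules.  `s` is the SPM profile.
# Returns list(records = list, skips = list).
.evaluateGene <- function(gene, s, labels, thr, reportAllK,
                          kMaxSel, kMaxRep) {
  n <- length(s)
  records <- list()
  skips <- list()

  ## specific: every sample whose SPM strictly exceeds the cut-off
  for (i in which(s > thr@specificSpmMin)) {
    records[[length(records) + 1L]] <-
      .newCallRecord(gene, "specific", 1L, labels[i], s[i])
  }

  ## selective: smallest k in range whose top-k samples (by SPM, ties by
  ## column order) all exceed the per-sample cut-off with subset CTM above
  ## the enrichment cut-off; with reportAllK every qualifying k is kept
  ordDesc <- order(-s, seq_len(n))
  for (k in seq.int(thr@selectiveKMin, kMaxSel)) {
    top <- ordDesc[seq_len(k)]
    if (!all(s[top] > thr@selectiveSpmMin)) break  # larger k only adds smaller SPMs
    ctmK <- sqrt(sum(s[top]^2))
    if (ctmK > thr@selectiveCtmMin) {
      records[[length(records) + 1L]] <-
        .newCallRecord(gene, "selective", k, labels[top], s[top], ctm = ctmK)
      if (!reportAllK) break
    }
  }

  ## housekeeping: dispersion of the SPM profile below the cut-off
  d <- stats::sd(s) * sqrt(n)
  if (d < thr@housekeepingDpmMax) {
    records[[length(records) + 1L]] <-
      .newCallRecord(gene, "housekeeping", n, labels, s, dpm = d)
  }

  ## repressed: smallest k in range whose bottom-k samples (by SPM, ties by
  ## column order) all fall below the per-sample cut-off with RPM below the
  ## ratio cut-off.  A k whose expression group still contains a zero has no
  ## defined RPM and simply fails (the zeros are absorbed as k grows); if
  ## every candidate k is undefined the gene is skipped for this class.
  ordAsc <- order(s, seq_len(n))
  anyDefined <- FALSE
  for (k in seq.int(thr@repressedKMin, kMaxRep)) {
    bottom <- ordAsc[seq_len(k)]
    expressionGroup <- ordAsc[seq.int(k + 1L, n)]
    if (!all(s[bottom] < thr@repressedSpmMax)) break  # larger k only adds larger SPMs
    spmExpMin <- s[expressionGroup[1L]]  # ascending order: first is the min
    if (spmExpMin == 0) next  # RPM undefined at this k
    anyDefined <- TRUE
    rpmK <- s[bottom[k]] / spmExpMin
    if (rpmK < thr@repressedRpmMax) {
      records[[length(records) + 1L]] <-
        .newCallRecord(gene, "repressed", k, labels[bottom], s[bottom],
                       rpm = rpmK)
      if (!reportAllK) break
    }
  }
  if (!anyDefined && sum(s == 0) > kMaxRep) {
    skips[[length(skips) + 1L]] <- list(
      gene = gene, class = "repressed",
      reason = sprintf("RPM undefined for every k in %d..%d: %d zero-expression samples exceed the maximum repressed-group size",
                       thr@repressedKMin, kMaxRep, sum(s == 0)))
  }

  list(records = records, skips = skips)
}

.effectiveKMax <- function(kMax, n, class, warnClip = TRUE) {
  if (kMax >= n) {
    if (warnClip) {
      warning(sprintf("%s kMax (%d) >= number of samples (%d); clipped to %d",
                      class, kMax, n, n - 1L), call. = FALSE)
    }
    n - 1L
  } else {
    kMax
  }
}

.profileCalls <- function(x, thresholds, sampleLabels, geneId,
                          clampNegatives, classes, reportAllK = FALSE) {
  x <- .checkProfile(x, clampNegatives)
  n <- length(x)
  if (is.null(sampleLabels)) {
    sampleLabels <- names(x)
    if (is.null(sampleLabels)) sampleLabels <- paste0("S", seq_len(n))
  }
  if (length(sampleLabels) != n || anyDuplicated(sampleLabels)) {
    .stopValidation("sampleLabels must be %d unique labels", n)
  }
  thr <- thresholds
  validObject(thr)
  s <- x / sqrt(sum(x^2))
  res <- .evaluateGene(geneId, s, sampleLabels, thr, reportAllK,
                       kMaxSel = .effectiveKMax(thr@selectiveKMax, n, "selective",
                                                warnClip = "selective" %in% classes),
                       kMaxRep = .effectiveKMax(thr@repressedKMax, n, "repressed",
                                                warnClip = "repressed" %in% classes))
  keep <- vapply(res$records, function(r) r$pattern %in% classes, logical(1))
  .recordsToDataFrame(res$records[keep])
}

#' Per-profile pattern calls
#'
#' Apply one class rule to a single expression profile.  These are the
#' building blocks of [classifyPatterns()]; each returns a call table with
#' zero or more rows (`callSpecific` can return one row per qualifying
#' sample; the other three return at most one row, for the smallest
#' qualifying subset size unless `reportAllK = TRUE`).
#'
#' @param x Numeric vector of nonnegative expression values, length >= 2.
#' @param thresholds A [PatternThresholds-class] object.
#' @param sampleLabels Optional sample labels (defaults to `names(x)` or
#'   `S1..Sn`).
#' @param geneId Gene identifier stamped on the calls.
#' @param clampNegatives Floor negative values at zero instead of erroring.
#' @param reportAllK Report every qualifying subset size, not only the
#'   smallest.
#' @return A [S4Vectors::DataFrame] of calls (see
#'   [PatternCallSet-class] for the columns).
#' @examples
#' callSpecific(c(0, 0, 5, 0))        # one call on sample 3, SPM = 1
#' callHousekeeping(c(5, 5, 5, 5))    # DPM = 0 < 0.3
#' callSelective(c(5, 5, 0, 0, 0, 0, 0))
#' callRepressed(c(0, 10, 10, 10, 10))
#' @name profile-calls
NULL

#' @rdname profile-calls
#' @export
callSpecific <- function(x, thresholds = patternThresholds(),
                         sampleLabels = NULL, geneId = "gene",
                         clampNegatives = FALSE) {
  .profileCalls(x, thresholds, sampleLabels, geneId, clampNegatives,
                classes = "specific")
}

#' @rdname profile-calls
#' @export
callSelective <- function(x, thresholds = patternThresholds(),
                          sampleLabels = NULL, geneId = "gene",
                          clampNegatives = FALSE, reportAllK = FALSE) {
  .profileCalls(x, thresholds, sampleLabels, geneId, clampNegatives,
                classes = "selective", reportAllK = reportAllK)
}

#' @rdname profile-calls
#' @export
callHousekeeping <- function(x, thresholds = patternThresholds(),
                             sampleLabels = NULL, geneId = "gene",
                             clampNegatives = FALSE) {
  .profileCalls(x, thresholds, sampleLabels, geneId, clampNegatives,
                classes = "housekeeping")
}

#' @rdname profile-calls
#' @export
callRepressed <- function(x, thresholds = patternThresholds(),
                          sampleLabels = NULL, geneId = "gene",
                          clampNegatives = FALSE, reportAllK = FALSE) {
  .profileCalls(x, thresholds, sampleLabels, geneId, clampNegatives,
                classes = "repressed", reportAllK = reportAllK)
}

#' Classify every gene of an expression matrix into pattern classes
#'
#' Runs the four pattern rules (specific, selective, housekeeping,
#' repressed) independently over each row of a nonnegative genes-by-samples
#' matrix and collects the qualifying calls.  Genes whose statistics are
#' undefined (all-zero profile, missing values, repression measure undefined
#' for every candidate subset size) are skipped and logged, never fatal.
#' Output order is deterministic: genes in row order, classes in the fixed
#' order specific, selective, housekeeping, repressed.
#'
#' @param x A numeric matrix (genes in rows, samples in columns) with unique
#'   column names, or a [SummarizedExperiment::SummarizedExperiment] (the
#'   assay named by `assayName`, default the first, is used).
#' @param thresholds A [PatternThresholds-class] object.
#' @param datasetId Dataset label stamped on the calls.
#' @param reportAllK For selective/repressed calls, report every qualifying
#'   subset size instead of only the smallest.
#' @param clampNegatives Floor negative values at zero instead of erroring.
#' @param verbose Print a per-class summary to the console.
#' @param ... Passed between methods.
#' @param assayName Assay to classify when `x` is a SummarizedExperiment.
#' @return A [PatternCallSet-class].
#' @examples
#' m <- rbind(tissueA = c(0, 0, 50, 0, 0, 0),
#'            steady  = c(9, 10, 11, 10, 9, 10))
#' colnames(m) <- paste0("T", 1:6)
#' classifyPatterns(m, datasetId = "toy")
#' @aliases classifyPatterns,matrix-method
#'   classifyPatterns,SummarizedExperiment-method
#' @rdname classifyPatterns
#' @export
setMethod("classifyPatterns", "matrix",
  function(x, thresholds = patternThresholds(), datasetId = "dataset",
           reportAllK = FALSE, clampNegatives = FALSE, verbose = FALSE, ...) {
    if (nrow(x) == 0L || ncol(x) < 2L) {
      .stopValidation("expression matrix must have at least 1 gene and 2 samples")
    }
    validObject(thresholds)
    labels <- colnames(x)
    if (is.null(labels)) labels <- paste0("S", seq_len(ncol(x)))
    if (anyDuplicated(labels)) {
      .stopValidation("duplicate sample label(s): %s",
                      paste(unique(labels[duplicated(labels)]), collapse = ", "))
    }
    genes <- rownames(x)
    if (is.null(genes)) genes <- paste0("gene_", seq_len(nrow(x)))
    n <- ncol(x)
    kMaxSel <- .effectiveKMax(thresholds@selectiveKMax, n, "selective")
    kMaxRep <- .effectiveKMax(thresholds@repressedKMax, n, "repressed")

    records <- vector("list", nrow(x))
    skips <- list()
    for (g in seq_len(nrow(x))) {
      prof <- x[g, ]
      cleaned <- tryCatch(.checkProfile(prof, clampNegatives, what = genes[g]),
                          patternGenesUndefinedStatistic = function(e) e,
                          patternGenesValidationError = function(e) {
                            if (anyNA(prof)) e else stop(e)
                          })
      if (inherits(cleaned, "condition")) {
        skips[[length(skips) + 1L]] <-
          list(gene = genes[g], class = "all", reason = conditionMessage(cleaned))
        next
      }
      s <- cleaned / sqrt(sum(cleaned^2))
      res <- .evaluateGene(genes[g], s, labels, thresholds, reportAllK,
                           kMaxSel, kMaxRep)
      records[[g]] <- res$records
      skips <- c(skips, res$skips)
    }
    records <- unlist(records, recursive = FALSE)
    calls <- .recordsToDataFrame(records)
    ## deterministic order: gene row order, then class order
    geneRank <- match(calls$gene, genes)
    calls <- calls[order(geneRank, as.integer(calls$pattern)), , drop = FALSE]
    cs <- new("PatternCallSet", calls = calls,
              skipped = .skipsToDataFrame(skips),
              thresholds = thresholds, datasetId = datasetId)
    if (verbose) {
      message(sprintf("classified %d gene(s): %s; skipped %d",
                      nrow(x),
                      paste(sprintf("%s %d", .patternClassLevels,
                                    table(calls$pattern)), collapse = ", "),
                      nrow(cs@skipped)))
    }
    cs
  })

#' @rdname classifyPatterns
#' @export
setMethod("classifyPatterns", "SummarizedExperiment",
  function(x, thresholds = patternThresholds(), datasetId = "dataset",
           assayName = NULL, ...) {
    a <- if (is.null(assayName)) SummarizedExperiment::assay(x)
         else SummarizedExperiment::assay(x, assayName)
    classifyPatterns(as.matrix(a), thresholds = thresholds,
                     datasetId = datasetId, ...)
  })

#' SPM matrix of an expression matrix
#'
#' Row-wise SPM transformation: each gene's profile is mapped to the unit
#' sphere.  All-zero rows yield NA with a warning (the statistic is
#' undefined there).
#'
#' @param x A numeric genes-by-samples matrix or a
#'   [SummarizedExperiment::SummarizedExperiment].
#' @param clampNegatives Floor negative values at zero instead of erroring.
#' @param ... Passed between methods.
#' @return A matrix of SPM values with the same dimensions and dimnames.
#' @aliases spmMatrix,matrix-method spmMatrix,SummarizedExperiment-method
#' @rdname spmMatrix
#' @export
setMethod("spmMatrix", "matrix", function(x, clampNegatives = FALSE, ...) {
  if (!is.numeric(x) || ncol(x) < 2L) {
    .stopValidation("x must be a numeric matrix with at least 2 columns")
  }
  if (any(x < 0, na.rm = TRUE)) {
    if (clampNegatives) x[x < 0] <- 0
    else .stopValidation("matrix contains negative values (use clampNegatives = TRUE to floor them)")
  }
  norms <- sqrt(rowSums(x^2))
  zero <- !is.na(norms) & norms == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero gene(s): SPM undefined, set to NA",
            call. = FALSE)
    norms[zero] <- NA_real_
  }
  x / norms
})

#' @rdname spmMatrix
#' @export
setMethod("spmMatrix", "SummarizedExperiment", function(x, ...) {
  spmMatrix(as.matrix(SummarizedExperiment::assay(x)), ...)
})
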