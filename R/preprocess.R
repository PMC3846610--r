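# Preprocessing of raw expression tables.
#
# Pipeline order is fixed: detection-call zeroing -> missing-cell policy ->
# replicate averaging -> probeset collapse.  The collapse therefore ranks
# probesets on the values classification will actually see.

#' Zero out absent/marginal detection calls
#'
#' Microarray tables that ship Absent/Marginal/Present (A/M/P) detection
#' calls are normalised by setting a cell's expression value to 0 when its
#' call is A or M; P cells are untouched.  The input is not mutated.
#'
#' @param values Numeric matrix (probesets/genes by samples).
#' @param calls Character matrix of the same shape with entries "A", "M" or
#'   "P" (NA entries leave the value untouched).
#' @return The values matrix with flagged cells set to 0.
#' @examples
#' v <- matrix(c(7.2, 1, 3, 4), 2, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' f <- matrix(c("A", "P", "P", "M"), 2, 2)
#' applyDetectionCalls(v, f)
#' @export
applyDetectionCalls <- function(values, calls) {
  if (!is.matrix(values) || !is.numeric(values)) {
    .stopValidation("values must be a numeric matrix")
  }
  if (!is.matrix(calls) || !identical(dim(calls), dim(values))) {
    .stopValidation("calls must be a matrix congruent with values (%d x %d)",
                    nrow(values), ncol(values))
  }
  known <- calls %in% c("A", "M", "P") | is.na(calls)
  if (!all(known)) {
    bad <- which(!known, arr.ind = TRUE)[1L, ]
    .stopValidation("unknown detection call '%s' at row %d (%s), column %d (%s); expected A, M or P",
                    calls[bad[1L], bad[2L]], bad[1L],
                    rownames(values)[bad[1L]] %||% "?",
                    bad[2L], colnames(values)[bad[2L]] %||% "?")
  }
  out <- values
  out[!is.na(calls) & calls %in% c("A", "M")] <- 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average duplicate (replicate) sample columns
#'
#' Columns belonging to the same replicate group are replaced by their
#' arithmetic mean; singleton groups pass through unchanged.  Output column
#' order follows the first appearance of each group among the input columns.
#'
#' @param values Numeric matrix with unique column names.
#' @param grouping Named character vector mapping every sample label to its
#'   group label.
#' @return A matrix with one column per group.
#' @examples
#' m <- cbind(liver_1 = c(2, 1), liver_2 = c(4, 2), brain = c(6, 6))
#' averageReplicates(m, c(liver_1 = "liver", liver_2 = "liver", brain = "brain"))
#' @export
averageReplicates <- function(values, grouping) {
  if (!is.matrix(values) || is.null(colnames(values))) {
    .stopValidation("values must be a matrix with column names")
  }
  missing <- setdiff(colnames(values), names(grouping))
  if (length(missing)) {
    .stopValidation("grouping is missing sample(s): %s",
                    paste(missing, collapse = ", "))
  }
  groups <- as.character(grouping[colnames(values)])
  order1 <- unique(groups)  # first-appearance order
  out <- vapply(order1, function(g) {
    rowMeans(values[, groups == g, drop = FALSE])
  }, numeric(nrow(values)))
  if (nrow(values) == 1L) out <- matrix(out, nrow = 1L,
                                        dimnames = list(rownames(values), order1))
  colnames(out) <- order1
  rownames(out) <- rownames(values)
  out
}

#' Collapse probesets to genes by maximal standard deviation
#'
#' For a gene measured by several probesets, the probeset whose profile has
#' the largest sample standard deviation (divisor n - 1) is kept as the
#' gene's row; the others are dropped.  Ties keep the first probeset in
#' table order.  Probesets absent from the mapping are dropped (their count
#' is reported via the `"dropped"` attribute and a message).
#'
#' @param values Numeric matrix with probeset IDs as row names.
#' @param probesetMap A data.frame whose first two columns map probeset ID
#'   to gene symbol, or a named character vector (names = probesets).
#' @return A genes-by-samples matrix; attributes `"dropped"` (unmapped
#'   probeset count) and `"ties"` (gene symbols whose selection was tied).
#' @examples
#' m <- rbind(p1 = c(5, 5, 5), p2 = c(1, 9, 5), p3 = c(2, 2, 3))
#' collapseProbesets(m, c(p1 = "GENE1", p2 = "GENE1", p3 = "GENE2"))
#' @export
collapseProbesets <- function(values, probesetMap) {
  if (!is.matrix(values) || is.null(rownames(values))) {
    .stopValidation("values must be a matrix with probeset row names")
  }
  if (is.data.frame(probesetMap)) {
    map <- stats::setNames(as.character(probesetMap[[2L]]),
                           as.character(probesetMap[[1L]]))
  } else {
    map <- probesetMap
  }
  if (length(map) == 0L) {
    .stopValidation("probeset-to-gene mapping is empty")
  }
  genes <- unname(map[rownames(values)])
  unmapped <- is.na(genes) | genes == ""
  if (any(unmapped)) {
    message(sum(unmapped), " unmapped probeset(s) dropped during collapse")
  }
  kept <- values[!unmapped, , drop = FALSE]
  genes <- genes[!unmapped]
  sds <- apply(kept, 1L, stats::sd)
  ties <- character()
  pick <- vapply(split(seq_along(genes), factor(genes, levels = unique(genes))),
                 function(idx) {
                   best <- idx[which.max(sds[idx])]  # which.max: first on ties
                   if (sum(sds[idx] == sds[best]) > 1L) {
                     ties <<- c(ties, genes[best])
                   }
                   best
                 }, integer(1))
  if (length(ties)) {
    message("probeset SD tie(s) resolved by table order for: ",
            paste(ties, collapse = ", "))
  }
  out <- kept[pick, , drop = FALSE]
  rownames(out) <- genes[pick]
  attr(out, "dropped") <- sum(unmapped)
  attr(out, "ties") <- ties
  out
}

#' Validate an expression matrix against the dataset-quality guidelines
#'
#' Emits non-fatal warnings when the matrix falls short of the guidelines a
#' pattern-gene analysis assumes: fewer than 5 distinct samples, all-zero
#' gene profiles (their statistics are undefined and they will be skipped),
#' or negative values (which classification rejects unless clamped).
#' Computation is never blocked.
#'
#' @param values Numeric genes-by-samples matrix.
#' @param warn Emit each finding as an R warning (default) in addition to
#'   returning it.
#' @return Invisibly, a character vector of findings (length 0 when clean).
#' @export
validateExpressionMatrix <- function(values, warn = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    .stopValidation("values must be a numeric matrix")
  }
  findings <- character()
  if (ncol(values) < 5L) {
    findings <- c(findings,
                  sprintf("fewer than 5 samples (%d): pattern statistics are weakly determined",
                          ncol(values)))
  }
  zeroRows <- sum(rowSums(values != 0, na.rm = TRUE) == 0L)
  if (zeroRows > 0L) {
    findings <- c(findings,
                  sprintf("%d all-zero gene profile(s): statistics undefined, will be skipped",
                          zeroRows))
  }
  if (any(values < 0, na.rm = TRUE)) {
    findings <- c(findings,
                  sprintf("%d negative value(s): classification rejects these unless clampNegatives = TRUE",
                          sum(values < 0, na.rm = TRUE)))
  }
  if (warn) for (f in findings) warning(f, call. = FALSE)
  invisible(findings)
}

#' Full preprocessing pipeline for a raw expression table
#'
#' Applies, in order: detection-call zeroing (when `calls` is given), the
#' missing-cell policy (drop rows containing missing cells, or impute 0),
#' replicate averaging (when `replicateGroups` is given) and probeset
#' collapse (when `probesetMap` is given), then runs
#' [validateExpressionMatrix()].
#'
#' @param values Numeric matrix (probesets/genes by samples).
#' @param calls Optional A/M/P call matrix, congruent with `values`.
#' @param replicateGroups Optional named character vector sample -> group.
#' @param probesetMap Optional probeset -> gene mapping (data.frame or named
#'   vector).
#' @param missing Policy for missing cells: `"drop"` rows containing any
#'   (default) or `"zero"` to impute 0.
#' @param clampNegatives Floor negative values at zero.
#' @return A clean genes-by-samples matrix ready for [classifyPatterns()].
#' @export
preprocessExpression <- function(values, calls = NULL, replicateGroups = NULL,
                                 probesetMap = NULL,
                                 missing = c("drop", "zero"),
                                 clampNegatives = FALSE) {
  missing <- match.arg(missing)
  if (!is.null(calls)) values <- applyDetectionCalls(values, calls)
  if (anyNA(values)) {
    if (missing == "drop") {
      bad <- rowSums(is.na(values)) > 0L
      message(sum(bad), " row(s) with missing cells dropped")
      values <- values[!bad, , drop = FALSE]
    } else {
      values[is.na(values)] <- 0
    }
  }
  if (clampNegatives && any(values < 0)) values[values < 0] <- 0
  if (!is.null(replicateGroups)) values <- averageReplicates(values, replicateGroups)
  if (!is.null(probesetMap)) values <- collapseProbesets(values, probesetMap)
  validateExpressionMatrix(values)
  values
}
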