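#' Simulate an expression matrix with planted pattern genes
#'
#' Generates a nonnegative genes-by-samples matrix containing planted
#' specific, selective, housekeeping, repressed and unpatterned genes with
#' known truth labels, for testing the statistics and the classifier
#' without any external data.
#'
#' Mean structure per class: housekeeping and unpatterned genes sit at
#' `baseExpression` in every sample; specific genes at `baseExpression *
#' foldEnrichment` in one randomly chosen sample (background elsewhere);
#' selective genes at the enriched level in `kSelective` random samples;
#' repressed genes at `repressedFloor` (exact 0 by default) in `kRepressed`
#' random samples and background elsewhere.  Noise is multiplicative
#' lognormal with coefficient of variation `noiseCV`, mean 1 (expression
#' data are nonnegative and right-skewed); exact-zero cells stay exactly
#' zero.  Unpatterned genes differ from housekeeping genes only in intent:
#' they carry independent noise around background and no planted call, so
#' at low noise they are legitimately housekeeping-like.
#'
#' @param nSamples Number of samples (columns); at least 5.
#' @param classCounts Named integer vector with entries `specific`,
#'   `selective`, `housekeeping`, `repressed`, `unpatterned` (missing
#'   entries default to 0).
#' @param baseExpression Background expression level (arbitrary intensity
#'   units).
#' @param foldEnrichment Enriched level / background level for specific and
#'   selective genes; > 1.
#' @param noiseCV Coefficient of variation of the multiplicative lognormal
#'   noise (0 disables noise).
#' @param kSelective Number of enriched samples per selective gene.
#' @param kRepressed Number of near-zero samples per repressed gene.
#' @param repressedFloor Expression level of repressed samples (default
#'   exact 0; set a small positive value to exercise the RPM ratio away
#'   from 0).
#' @param seed Optional integer seed for reproducibility.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"expression"`, sample names `sample_01..`, and truth labels in
#'   `rowData`: `plantedClass` (factor, the five classes above) and
#'   `plantedSamples` ([IRanges::CharacterList]; empty for
#'   housekeeping/unpatterned genes, where no particular sample is
#'   implicated).
#' @examples
#' se <- simulatePatternMatrix(classCounts = c(specific = 3, housekeeping = 2),
#'                             noiseCV = 0, seed = 1)
#' SummarizedExperiment::rowData(se)$plantedClass
#' @export
simulatePatternMatrix <- function(nSamples = 12L,
                                  classCounts = c(specific = 100L,
                                                  selective = 100L,
                                                  housekeeping = 100L,
                                                  repressed = 100L,
                                                  unpatterned = 100L),
                                  baseExpression = 100,
                                  foldEnrichment = 20,
                                  noiseCV = 0.05,
                                  kSelective = 3L,
                                  kRepressed = 2L,
                                  repressedFloor = 0,
                                  seed = NULL) {
  classes <- c("specific", "selective", "housekeeping", "repressed",
               "unpatterned")
  if (is.null(names(classCounts)) ||
      !all(names(classCounts) %in% classes)) {
    .stopValidation("classCounts must be named with: %s",
                    paste(classes, collapse = ", "))
  }
  counts <- stats::setNames(integer(length(classes)), classes)
  counts[names(classCounts)] <- as.integer(classCounts)
  if (any(counts < 0L) || sum(counts) == 0L) {
    .stopValidation("classCounts must be nonnegative with at least one gene")
  }
  nSamples <- as.integer(nSamples)
  if (nSamples < 5L) {
    .stopValidation("nSamples must be at least 5 (pattern analysis needs a sample series)")
  }
  if (foldEnrichment <= 1) .stopValidation("foldEnrichment must exceed 1")
  if (noiseCV < 0) .stopValidation("noiseCV must be nonnegative")
  if (kSelective >= nSamples || kRepressed >= nSamples ||
      kSelective < 1L || kRepressed < 1L) {
    .stopValidation("kSelective and kRepressed must lie in [1, nSamples - 1]")
  }
  if (repressedFloor < 0) .stopValidation("repressedFloor must be nonnegative")
  if (!is.null(seed)) set.seed(as.integer(seed))

  sampleNames <- sprintf("sample_%02d", seq_len(nSamples))
  nGenes <- sum(counts)
  plantedClass <- factor(rep(classes, counts), levels = classes)
  geneIds <- sprintf("%s_%03d", plantedClass,
                     unlist(lapply(counts, seq_len), use.names = FALSE))

  high <- baseExpression * foldEnrichment
  mu <- matrix(baseExpression, nrow = nGenes, ncol = nSamples,
               dimnames = list(geneIds, sampleNames))
  plantedSamples <- vector("list", nGenes)
  for (g in seq_len(nGenes)) {
    cls <- as.character(plantedClass[g])
    planted <- integer(0)
    if (cls == "specific") {
      planted <- sample.int(nSamples, 1L)
      mu[g, planted] <- high
    } else if (cls == "selective") {
      planted <- sort(sample.int(nSamples, kSelective))
      mu[g, planted] <- high
    } else if (cls == "repressed") {
      planted <- sort(sample.int(nSamples, kRepressed))
      mu[g, planted] <- repressedFloor
    }
    plantedSamples[[g]] <- sampleNames[planted]
  }

  values <- mu
  if (noiseCV > 0) {
    sdlog <- sqrt(log(1 + noiseCV^2))
    noise <- matrix(stats::rlnorm(nGenes * nSamples,
                                  meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    nrow = nGenes)
    values <- mu * noise  # exact zeros stay exactly zero
  }

  SummarizedExperiment::SummarizedExperiment(
    assays = list(expression = values),
    rowData = S4Vectors::DataFrame(
      plantedClass = plantedClass,
      plantedSamples = IRanges::CharacterList(plantedSamples),
      row.names = geneIds))
}

#' Write a simulated dataset as matrix + truth TSVs
#'
#' Emits the same TSV dialect [readExpressionTable()] reads, plus a truth
#' table with columns `gene`, `class`, `samples` (comma-joined).
#'
#' @param se A SummarizedExperiment from [simulatePatternMatrix()].
#' @param matrixPath,truthPath Output paths.
#' @return Invisibly, `c(matrixPath, truthPath)`.
#' @export
writeSyntheticData <- function(se, matrixPath, truthPath) {
  writeExpressionTable(as.matrix(SummarizedExperiment::assay(se)), matrixPath)
  rd <- SummarizedExperiment::rowData(se)
  truth <- data.frame(
    gene = rownames(se),
    class = as.character(rd$plantedClass),
    samples = vapply(rd$plantedSamples, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrixPath, truthPath))
}

#' Planted-call recovery rates of a classification
#'
#' For each planted pattern class, the fraction of planted genes that
#' received a call of that class on exactly the planted samples (specific,
#' selective, repressed) or on all samples (housekeeping).  Unpatterned
#' genes carry no planted call and are not scored.
#'
#' @param se The SummarizedExperiment returned by [simulatePatternMatrix()].
#' @param callSet A [PatternCallSet-class] from classifying its assay.
#' @return Named numeric vector of per-class recovery fractions (NA for
#'   classes with no planted genes).
#' @export
plantedRecovery <- function(se, callSet) {
  rd <- SummarizedExperiment::rowData(se)
  calls <- patternCalls(callSet)
  key <- paste0(calls$gene, "\r", as.character(calls$pattern))
  callSamples <- split(as.list(calls$samples), key)
  vapply(.patternClassLevels, function(cls) {
    planted <- which(rd$plantedClass == cls)
    if (length(planted) == 0L) return(NA_real_)
    hits <- vapply(planted, function(g) {
      got <- callSamples[[paste0(rownames(se)[g], "\r", cls)]]
      if (is.null(got)) return(FALSE)
      want <- rd$plantedSamples[[g]]
      if (cls == "housekeeping") want <- colnames(se)
      any(vapply(got, function(sm) setequal(sm, want), logical(1)))
    }, logical(1))
    mean(hits)
  }, numeric(1))
}
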