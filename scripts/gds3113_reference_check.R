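#!/usr/bin/env Rscript

# Reference-gene check on the 26-tissue human body-map GEO DataSet GDS3113.
# Requires the full SOFT table (not shipped here; download it once with:
#   https://ftp.ncbi.nlm.nih.gov/geo/datasets/GDS3nnn/GDS3113/soft/GDS3113_full.soft.gz
# and gunzip it), then run:
#
#   Rscript scripts/gds3113_reference_check.R <path/to/GDS3113_full.soft>
#
# Prints the dispersion measure (DPM) of the classical reference genes
# GAPDH, PPIA, ACTB and GOLGA1, plus GAPDH's SPM in skeletal muscle and
# PRM1's SPM in testis, computed through the standard pipeline: A/M/P
# zeroing (if call columns are present), replicate averaging by subset,
# probeset collapse by maximal standard deviation.

suppressPackageStartupMessages(library(PatternGenes))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 1L) stop("usage: gds3113_reference_check.R <GDS3113_full.soft>")

gds <- readGDS(args[[1L]])
mat <- preprocessExpression(gds$values, calls = gds$calls,
                            replicateGroups = gds$replicateGroups,
                            probesetMap = gds$probesetMap)

for (g in c("GAPDH", "PPIA", "ACTB", "GOLGA1")) {
  if (g %in% rownames(mat)) {
    cat(sprintf("DPM(%s) = %.2f\n", g, dpm(mat[g, ])))
  } else {
    cat(sprintf("%s not present after collapse\n", g))
  }
}
s <- spmMatrix(mat)
report <- function(gene, samplePattern) {
  hit <- grep(samplePattern, colnames(mat), ignore.case = TRUE)
  if (gene %in% rownames(mat) && length(hit)) {
    cat(sprintf("SPM(%s, %s) = %.2f\n", gene, colnames(mat)[hit[1L]],
                s[gene, hit[1L]]))
  }
}
report("GAPDH", "skeletal")
report("PRM1", "testis")
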