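# Shared fixture builders; everything is generated in code.

# random nonnegative profile with at least one positive value
randomProfile <- function(n, zeroFrac = 0.2) {
  x <- stats::runif(n, 0, 100)
  x[stats::runif(n) < zeroFrac] <- 0
  if (all(x == 0)) x[sample.int(n, 1L)] <- stats::runif(1, 1, 100)
  x
}

# independently coded cosine oracle: cos(theta) between the one-sample
# projection X_i and X, via the literal dot-product/norm definition
cosineOracle <- function(x, i) {
  xi <- numeric(length(x))
  xi[i] <- x[i]
  sum(xi * x) / (sqrt(sum(xi^2)) * sqrt(sum(x^2)))
}

toyMatrix <- function() {
  m <- rbind(
    spike   = c(0, 0, 50, 0, 0, 0, 0),
    steady  = c(9, 10, 11, 10, 9, 10, 10),
    duo     = c(40, 42, 0, 1, 0, 1, 0),
    dark    = c(0, 30, 31, 29, 30, 30, 30),
    silent  = c(0, 0, 0, 0, 0, 0, 0))
  colnames(m) <- paste0("T", 1:7)
  m
}

writeGdsFixture <- function(path, withCalls = TRUE, truncate = FALSE) {
  header <- if (withCalls) {
    "ID_REF\tIDENTIFIER\tGSM1\tGSM1_CALL\tGSM2\tGSM2_CALL\tGSM3\tGSM3_CALL"
  } else {
    "ID_REF\tIDENTIFIER\tGSM1\tGSM2\tGSM3"
  }
  rows <- if (withCalls) {
    c("p1\tGENEA\t5.0\tP\t6.0\tP\t0.4\tA",
      "p2\tGENEB\t1.0\tP\t1.2\tP\tnull\tM")
  } else {
    c("p1\tGENEA\t5.0\t6.0\t0.4",
      "p2\tGENEB\t1.0\t1.2\t1.1")
  }
  lines <- c(
    "^DATABASE = GeoMiame",
    "!Database_name = fixture",
    "^SUBSET = fix_1",
    "!subset_description = liver",
    "!subset_sample_id = GSM1,GSM2",
    "^SUBSET = fix_2",
    "!subset_description = brain",
    "!subset_sample_id = GSM3",
    "^DATASET = FIXTURE1",
    "!dataset_table_begin",
    header,
    rows)
  if (!truncate) lines <- c(lines, "!dataset_table_end")
  writeLines(lines, path)
  path
}
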