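test_that("absent/marginal detection calls zero the cell, present leaves it", {
  v <- matrix(c(7.2, 1.5, 0, 3.3), 2, 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  f <- matrix(c("A", "P", "M", "P"), 2, 2)
  out <- applyDetectionCalls(v, f)
  expect_identical(out["p1", "s1"], 0)    # 7.2 flagged A
  expect_identical(out["p2", "s1"], 1.5)  # P unchanged
  expect_identical(out["p1", "s2"], 0)    # 0 flagged M stays 0
  expect_identical(out["p2", "s2"], 3.3)
  expect_identical(v["p1", "s1"], 7.2)    # input not mutated

  fBad <- f; fBad[2, 2] <- "X"
  expect_error(applyDetectionCalls(v, fBad), "row 2.*column 2",
               class = "patternGenesValidationError")
  expect_error(applyDetectionCalls(v, f[, 1, drop = FALSE]), "congruent",
               class = "patternGenesValidationError")

  # idempotent: re-applying the same calls changes nothing
  expect_identical(applyDetectionCalls(out, f), out)
})

test_that("replicate averaging takes the arithmetic mean in first-appearance order", {
  m <- cbind(liv_1 = c(2, 1), liv_2 = c(4, 2), brain = c(6, 6), liv_3 = c(6, 9))
  rownames(m) <- c("g1", "g2")
  g <- c(liv_1 = "liver", liv_2 = "liver", liv_3 = "liver", brain = "brain")
  out <- averageReplicates(m, g)
  expect_identical(colnames(out), c("liver", "brain"))  # first appearance
  expect_identical(out["g1", "liver"], 4)               # mean(2, 4, 6)
  expect_identical(out["g2", "liver"], 4)               # mean(1, 2, 9)
  expect_identical(out[, "brain"], c(g1 = 6, g2 = 6))

  # all-singleton grouping is the identity (up to relabelling)
  ident <- setNames(colnames(m), colnames(m))
  expect_identical(averageReplicates(m, ident), m)
  # and averaging its own output again is a no-op
  gOut <- setNames(colnames(out), colnames(out))
  expect_identical(averageReplicates(out, gOut), out)

  expect_error(averageReplicates(m, g[-1]), "liv_1",
               class = "patternGenesValidationError")
})

test_that("probeset collapse keeps the largest-SD profile per gene", {
  m <- rbind(p1 = c(5, 5, 5), p2 = c(1, 9, 5), p3 = c(2, 2, 3),
             p4 = c(9, 9, 9), p5 = c(0, 1, 2))
  map <- c(p1 = "G1", p2 = "G1", p3 = "G2", p5 = "G3")  # p4 unmapped
  expect_message(out <- collapseProbesets(m, map), "1 unmapped")
  expect_identical(rownames(out), c("G1", "G2", "G3"))
  expect_identical(unname(out["G1", ]), c(1, 9, 5))  # SD 4 beats SD 0
  expect_identical(attr(out, "dropped"), 1L)
  # collapse never invents values: every row equals an input row
  for (g in rownames(out)) {
    expect_true(any(apply(m, 1, function(r) all(r == out[g, ]))))
  }

  # single-probeset gene passes through
  expect_identical(unname(out["G2", ]), c(2, 2, 3))

  # equal SDs: first probeset in table order wins, tie is reported
  m2 <- rbind(a = c(1, 3), b = c(4, 6))
  expect_message(out2 <- collapseProbesets(m2, c(a = "G", b = "G")), "tie")
  expect_identical(unname(out2["G", ]), c(1, 3))

  expect_error(collapseProbesets(m, character(0)),
               class = "patternGenesValidationError")

  # idempotent: collapsing a collapsed matrix under the identity map
  idMap <- setNames(rownames(out), rownames(out))
  again <- collapseProbesets(out, idMap)
  expect_equal(unname(again), unname(out[rownames(again), ]),
               ignore_attr = TRUE)
})

test_that("dataset validation warns without blocking", {
  m4 <- matrix(runif(8, 1, 5), 2, 4)
  expect_warning(f <- validateExpressionMatrix(m4), "fewer than 5")
  expect_length(f, 1L)

  clean <- matrix(runif(12, 1, 5), 2, 6)
  expect_silent(f2 <- validateExpressionMatrix(clean))
  expect_length(f2, 0L)

  mz <- rbind(matrix(runif(18, 1, 5), 3, 6), matrix(0, 3, 6))
  expect_warning(f3 <- validateExpressionMatrix(mz), "3 all-zero")
})

test_that("the pipeline runs call-zeroing, averaging and collapse in order", {
  v <- rbind(p1 = c(10, 12, 3, 3, 3, 3),
             p2 = c(5, 6, 1, 1, 1, 1),
             p3 = c(1, 100, 1, 1, 1, 1))
  colnames(v) <- c("a1", "a2", "b", "c", "d", "e")
  calls <- matrix("P", 3, 6, dimnames = dimnames(v))
  calls["p3", "a2"] <- "A"  # the spike that made p3 high-SD is absent
  groups <- setNames(c("a", "a", "b", "c", "d", "e"), colnames(v))
  map <- c(p1 = "G", p2 = "G", p3 = "G")

  out <- suppressWarnings(
    preprocessExpression(v, calls = calls, replicateGroups = groups,
                         probesetMap = map))
  # zeroing happens before collapse: p3's SD collapses with its spike, so
  # p1 (SD on averaged values) is selected
  expect_identical(rownames(out), "G")
  expect_identical(unname(out["G", ]), c(11, 3, 3, 3, 3))

  # rows with missing cells are dropped by default, imputed with "zero"
  v2 <- v; v2["p2", "b"] <- NA
  expect_message(outDrop <- suppressWarnings(preprocessExpression(v2)),
                 "1 row")
  expect_identical(rownames(outDrop), c("p1", "p3"))
  outZero <- suppressWarnings(preprocessExpression(v2, missing = "zero"))
  expect_identical(outZero["p2", "b"], 0)
})
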