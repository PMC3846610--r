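test_that("spm matches hand-computed cosines and its closed-form cases", {
  # single-sample expression is perfectly specific
  expect_identical(spm(c(0, 0, 5, 0), 3), 1)
  # uniform profile on n samples gives 1/sqrt(n)
  expect_identical(spm(c(1, 1, 1, 1), 2), 0.5)
  # hand oracle: 3/sqrt(25), 4/sqrt(25)
  expect_equal(spm(c(3, 4), 1), 0.6)
  expect_equal(spm(c(3, 4), 2), 0.8)
})

test_that("spmProfile maps onto the unit sphere elementwise", {
  expect_equal(spmProfile(c(0, 0, 5, 0)), c(0, 0, 1, 0))
  expect_equal(spmProfile(c(3, 4)), c(0.6, 0.8))
  expect_equal(spmProfile(rep(2, 9)), rep(1 / 3, 9))
  x <- c(5, 0, 2, 7, 1)
  expect_equal(spmProfile(x), vapply(seq_along(x), function(i) spm(x, i),
                                     numeric(1)))
})

test_that("profile validation rejects degenerate inputs with typed errors", {
  expect_error(spm(c(0, 0, 0), 1), class = "patternGenesUndefinedStatistic")
  expect_error(spm(c(1, -2, 3), 1), class = "patternGenesValidationError")
  expect_error(spm(c(1, NA, 3), 1), class = "patternGenesValidationError")
  expect_error(spm(5, 1), class = "patternGenesValidationError")   # n < 2
  expect_error(spm(c(1, 2), 3), class = "patternGenesValidationError")
  expect_error(dpm(c(1, -1)), class = "patternGenesValidationError")
  # explicit clamping floors negatives at zero instead
  expect_identical(spm(c(1, -2, 0), 1, clampNegatives = TRUE), 1)
})

test_that("dpm is 0 for uniform, 1 for single-spike, and matches hand values", {
  for (n in 2:10) {
    expect_identical(dpm(rep(7.3, n)), 0)
    spike <- numeric(n); spike[sample.int(n, 1)] <- runif(1, 1, 50)
    # sd of a unit basis vector is 1/sqrt(n), so sd * sqrt(n) = 1
    expect_equal(dpm(spike), 1, tolerance = 1e-12)
  }
  # SPM = (0.6, 0.8), mean 0.7, s = sqrt(0.02), times sqrt(2) = 0.2
  expect_equal(dpm(c(3, 4)), 0.2)
})

test_that("ctm reduces to spm for singletons and to 1 on the full set", {
  x <- c(3, 4)
  expect_equal(ctm(x, 2), 0.8)
  expect_equal(ctm(x, c(1, 2)), 1)
  y <- randomProfile(12)
  expect_equal(ctm(y, seq_along(y)), 1, tolerance = 1e-12)
  expect_equal(ctm(y, 5), spm(y, 5))
  expect_error(ctm(x, integer(0)), class = "patternGenesValidationError")
})

test_that("ctmFromSpm reproduces the published multi-tissue SPM worked examples", {
  # three printed SPM subsets each carry essentially the whole profile
  expect_equal(round(ctmFromSpm(c(0.66, 0.47, 0.59)), 1), 1.0)
  expect_equal(round(ctmFromSpm(c(0.78, 0.62)), 1), 1.0)
  expect_equal(round(ctmFromSpm(c(0.50, 0.52, 0.69)), 1), 1.0)
})

test_that("rpm contrasts the repressed group against the expression floor", {
  expect_identical(rpm(c(0, 0, 5, 7), c(1, 2)), 0)
  # the profile norm cancels: (1/||X||) / (10/||X||) = 0.1
  expect_equal(rpm(c(1, 10, 10, 10), 1), 0.1)
  expect_equal(rpm(c(2, 4, 4), 1), 0.5)
  # zero inside the expression group leaves RPM undefined
  expect_error(rpm(c(0, 0, 5, 7), 1), class = "patternGenesUndefinedStatistic")
  # repressed group must be a proper subset
  expect_error(rpm(c(1, 2), c(1, 2)), class = "patternGenesValidationError")
  # warn when the chosen group is not the lowest-expression samples
  expect_warning(rpm(c(1, 10, 10, 10), 2), "lowest-expression")
})

test_that("fractional expression and SUM match the proportion baseline", {
  expect_identical(expressionFraction(c(1, 1, 1, 1), 2), 0.25)
  expect_identical(expressionFraction(c(0, 0, 5, 0), 3), 1)
  expect_equal(expressionFraction(c(3, 4), 2), 4 / 7)
  expect_identical(fractionSum(c(3, 4), c(1, 2)), 1)
  expect_equal(fractionSum(c(1, 2, 3, 4), c(3, 4)), 0.7)
})

test_that("spmMatrix transforms rows and flags all-zero genes as NA", {
  m <- toyMatrix()
  expect_warning(s <- spmMatrix(m), "all-zero")
  expect_identical(dim(s), dim(m))
  expect_equal(s["spike", ],
               c(T1 = 0, T2 = 0, T3 = 1, T4 = 0, T5 = 0, T6 = 0, T7 = 0))
  expect_true(all(is.na(s["silent", ])))
  expect_equal(unname(s["duo", ]), spmProfile(m["duo", ]), ignore_attr = TRUE)
})
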