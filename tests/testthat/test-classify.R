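thrDefault <- patternThresholds()

test_that("specific calls fire on one dominant sample, strictly above the cut-off", {
  calls <- callSpecific(c(0, 0, 5, 0))
  expect_identical(nrow(calls), 1L)
  expect_identical(as.character(calls$pattern), "specific")
  expect_identical(calls$samples[[1]], "S3")
  expect_identical(calls$spm[[1]], 1)

  expect_identical(nrow(callSpecific(c(1, 1, 1, 1))), 0L)  # SPM = 0.5 everywhere

  # SPM_1 = 9.5/sqrt(90.25 + 3) ~ 0.984 > 0.9
  calls <- callSpecific(c(9.5, 1, 1, 1))
  expect_identical(calls$samples[[1]], "S1")
  expect_gt(calls$spm[[1]], 0.9)
})

test_that("housekeeping calls require low dispersion across all samples", {
  calls <- callHousekeeping(rep(8, 6))
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$dpm[1], 0)
  expect_identical(calls$samples[[1]], paste0("S", 1:6))

  expect_identical(nrow(callHousekeeping(c(0, 0, 9, 0))), 0L)  # DPM = 1

  calls <- callHousekeeping(c(3, 4))  # DPM = 0.2 < 0.3
  expect_identical(nrow(calls), 1L)
  expect_equal(calls$dpm[1], 0.2)
})

test_that("selective calls report the smallest qualifying k of top-SPM samples", {
  calls <- callSelective(c(5, 5, 0, 0, 0, 0, 0))
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$k[1], 2L)
  expect_identical(sort(calls$samples[[1]]), c("S1", "S2"))
  expect_equal(calls$ctm[1], 1)

  # uniform over 10 samples: top-6 CTM = sqrt(6/10) < 0.9
  expect_identical(nrow(callSelective(rep(3, 10))), 0L)
  # second-ranked SPM is 0, fails the per-sample clause at every k
  expect_identical(nrow(suppressWarnings(callSelective(c(0, 0, 5, 0)))), 0L)

  # with reportAllK every qualifying k is listed, smallest first
  x <- c(10, 10, 10, 0.1, 0.1, 0.1, 0.1, 0.1)
  one <- callSelective(x)
  all <- callSelective(x, reportAllK = TRUE)
  expect_identical(one$k[1], min(all$k))
  expect_gte(nrow(all), nrow(one))
})

test_that("repressed calls absorb zeros into the candidate group as k grows", {
  calls <- suppressWarnings(callRepressed(c(0, 10, 10, 10, 10)))
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$k[1], 1L)
  expect_identical(calls$samples[[1]], "S1")
  expect_identical(calls$rpm[1], 0)

  expect_identical(nrow(callRepressed(rep(5, 8))), 0L)  # RPM = 1

  # k = 1 boundary: SPM_1 = 1/sqrt(301) < 0.1 and RPM = 0.1 < 0.2
  calls <- suppressWarnings(callRepressed(c(1, 10, 10, 10)))
  expect_identical(nrow(calls), 1L)
  expect_equal(calls$rpm[1], 0.1)

  # two planted zeros: k = 1 has an undefined RPM (zero left in the
  # expression group); the call lands at k = 2
  calls <- callRepressed(c(0, 0, 10, 10, 10, 10, 10))
  expect_identical(calls$k[1], 2L)
  expect_identical(sort(calls$samples[[1]]), c("S1", "S2"))
})

test_that("thresholds are strict: statistics exactly at the cut-off never call", {
  # 9/sqrt(81 + 16 + 1 + 1 + 1) = 9/10 = 0.9 exactly
  x <- c(9, 4, 1, 1, 1)
  expect_identical(spm(x, 1), 0.9)
  expect_identical(nrow(callSpecific(x)), 0L)
  expect_identical(nrow(callSpecific(x, patternThresholds(specificSpmMin = 0.89))), 1L)

  # 1/sqrt(1 + 49 + 49 + 1) = 0.1 exactly: not strictly below 0.1
  y <- c(1, 7, 7, 1)
  expect_identical(spm(y, 1), 0.1)
  expect_identical(nrow(suppressWarnings(callRepressed(y))), 0L)

  # uniform profile: DPM exactly 0 is not strictly below a 0 cut-off
  expect_identical(nrow(callHousekeeping(rep(2, 6),
                                         patternThresholds(housekeepingDpmMax = 0))),
                   0L)
  # and a threshold set to the computed statistic never calls
  z <- c(3, 4)
  expect_identical(nrow(callHousekeeping(z, patternThresholds(housekeepingDpmMax = dpm(z)))),
                   0L)
  sel <- c(5, 5, 0.1, 0.1, 0.1, 0.1, 0.1)
  ctmTop2 <- ctm(sel, order(-spmProfile(sel))[1:2])
  expect_identical(nrow(callSelective(sel, patternThresholds(selectiveCtmMin = ctmTop2))),
                   0L)
  rep1 <- c(1, 10, 10, 10)
  expect_identical(nrow(suppressWarnings(callRepressed(rep1, patternThresholds(repressedRpmMax = rpm(rep1, 1))))),
                   0L)
})

test_that("classifyPatterns applies all four rules independently per gene", {
  m <- toyMatrix()
  cs <- classifyPatterns(m, datasetId = "toy")
  df <- as.data.frame(cs)

  expect_s4_class(cs, "PatternCallSet")
  expect_identical(datasetId(cs), "toy")
  # spike: specific on T3
  expect_true(any(df$gene == "spike" & df$pattern == "specific" &
                    df$samples == "T3"))
  # steady: housekeeping over all samples
  expect_true(any(df$gene == "steady" & df$pattern == "housekeeping"))
  # duo: selective with k = 2 on its two high samples
  duo <- df[df$gene == "duo" & df$pattern == "selective", ]
  expect_identical(duo$k, 2L)
  # dark: repressed at k = 1 on its zero sample
  dark <- df[df$gene == "dark" & df$pattern == "repressed", ]
  expect_identical(dark$samples, "T1")
  # silent: no calls, one skip record
  expect_false("silent" %in% df$gene)
  skips <- skippedGenes(cs)
  expect_true(any(skips$gene == "silent" & grepl("all-zero", skips$reason)))

  # deterministic order: genes in row order, classes in fixed order
  expect_identical(df$gene, df$gene[order(match(df$gene, rownames(m)))])
})

test_that("a gene may carry several calls; repression skips are logged", {
  # expressed in one sample only: specific, and (once the zeros are all
  # absorbed into the candidate group) repressed on the remaining samples
  m <- matrix(c(0, 0, 5, 0), nrow = 1,
              dimnames = list("solo", paste0("S", 1:4)))
  cs <- suppressWarnings(classifyPatterns(m))
  pats <- as.character(patternCalls(cs)$pattern)
  expect_setequal(pats, c("specific", "repressed"))

  # more zeros than the largest candidate k: RPM undefined at every k
  m2 <- matrix(c(rep(0, 8), rep(10, 4)), nrow = 1,
               dimnames = list("mostlyoff", paste0("S", 1:12)))
  cs2 <- classifyPatterns(m2)
  expect_false("repressed" %in% as.character(patternCalls(cs2)$pattern))
  skips <- skippedGenes(cs2)
  expect_true(any(skips$gene == "mostlyoff" & skips$class == "repressed"))
})

test_that("degenerate sample counts clip the k ranges with a warning", {
  m <- matrix(c(5, 5, 0.1, 0.1), nrow = 1,
              dimnames = list("g", paste0("S", 1:4)))
  expect_warning(expect_warning(classifyPatterns(m), "clipped"), "clipped")
})

test_that("tightening a threshold never increases that class's call count", {
  set.seed(77)
  se <- simulatePatternMatrix(nSamples = 10,
                              classCounts = c(specific = 30, selective = 30,
                                              housekeeping = 30, repressed = 30,
                                              unpatterned = 30),
                              seed = 77)
  m <- as.matrix(SummarizedExperiment::assay(se))
  nOf <- function(cs, cls) sum(patternCalls(cs)$pattern == cls)
  base <- classifyPatterns(m)
  expect_lte(nOf(classifyPatterns(m, patternThresholds(specificSpmMin = 0.99)),
                 "specific"),
             nOf(base, "specific"))
  expect_lte(nOf(classifyPatterns(m, patternThresholds(housekeepingDpmMax = 0.1)),
                 "housekeeping"),
             nOf(base, "housekeeping"))
  expect_lte(nOf(classifyPatterns(m, patternThresholds(selectiveCtmMin = 0.99)),
                 "selective"),
             nOf(base, "selective"))
  expect_lte(nOf(classifyPatterns(m, patternThresholds(repressedRpmMax = 0.05)),
                 "repressed"),
             nOf(base, "repressed"))
})

test_that("threshold objects validate their slots", {
  expect_error(patternThresholds(specificSpmMin = 1.2), "\\[0, 1\\]")
  expect_error(patternThresholds(selectiveKMin = 4, selectiveKMax = 2),
               "kMin <= kMax")
  expect_error(classifyPatterns(matrix(numeric(0), 0, 0)),
               class = "patternGenesValidationError")
})
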