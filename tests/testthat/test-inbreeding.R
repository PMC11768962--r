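# Finite-sample inbreeding coefficient of the synthetic variety.

test_that("sample decomposition splits m into complete groups and leftovers", {
  d <- decomposeSample(15)
  expect_equal(nGroups(d), 3L)
  expect_equal(nLeftover(d), 3L)
  expect_equal(nGroups(decomposeSample(4)), 1L)
  expect_equal(nLeftover(decomposeSample(4)), 0L)
  expect_equal(nGroups(decomposeSample(1)), 0L)
  expect_equal(nLeftover(decomposeSample(1)), 1L)
  expect_error(decomposeSample(0), ">= 1")
  expect_error(decomposeSample(2.5), "integer")
})

test_that("the per-line grid reproduces the reference table", {
  # reference grid of l*F_SynL for m = 1..24, F in (0, .5, .75, .875, 1),
  # two decimals, rounded half-away-from-zero
  expected <- matrix(c(
    0.75, 0.88, 0.94, 0.97, 1.00,
    0.58, 0.79, 0.90, 0.95, 1.00,
    0.53, 0.76, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00,
    0.51, 0.76, 0.88, 0.94, 1.00,
    0.51, 0.75, 0.88, 0.94, 1.00,
    0.51, 0.75, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00,
    0.50, 0.75, 0.88, 0.94, 1.00), ncol = 5, byrow = TRUE)
  grid <- icTable()
  expect_equal(grid$m, 1:24)
  expect_equal(grid$e, rep(c(1L, 2L, 3L, 0L), 6))
  got <- as.matrix(grid[, 3:7])
  dimnames(got) <- NULL
  expect_equal(got, expected)
})

test_that("multiples of four hit the Hardy-Weinberg value exactly", {
  for (F in list(0, 0.5, rational(7, 8), rational(1, 3)))
    for (m in c(4, 8, 12, 24, 40))
      expect_true(perLineValue(syntheticIC(m, F)) == icAsymptote(F))
})

test_that("fully inbred lines give coefficient one at every sample size", {
  for (m in 1:12) {
    expect_true(perLineValue(syntheticIC(m, 1)) == 1)
    expect_true(fSynL(syntheticIC(m, 1, l = 5)) == rational(1, 5))
  }
})

test_that("per-line value is sandwiched and maximal only at m = 1", {
  for (F in list(0, 0.5, rational(7, 8))) {
    lo <- icAsymptote(F)
    hi <- meanSelfingIC(F)
    expect_true(perLineValue(syntheticIC(1, F)) == hi)
    for (m in 2:20) {
      v <- perLineValue(syntheticIC(m, F))
      expect_true(v >= lo)
      expect_true(v < hi)
    }
  }
})

test_that("within each leftover class the value decreases towards the limit", {
  for (F in list(0, 0.5)) {
    for (e in 1:3) {
      ms <- seq(e, 48, by = 4)
      ms <- ms[ms >= 1]
      vals <- lapply(ms, function(m) perLineValue(syntheticIC(m, F)))
      for (i in seq_len(length(vals) - 1))
        expect_true(vals[[i + 1]] < vals[[i]])
    }
    # convergence: within 0.01 of the limit from m = 8 on
    lim <- asNumeric(icAsymptote(F))
    devs <- vapply(8:200, function(m)
      abs(asNumeric(perLineValue(syntheticIC(m, F))) - lim), numeric(1))
    expect_true(all(devs < 0.01))
  }
})

test_that("the variety coefficient scales exactly as 1/l", {
  for (m in c(1, 5, 7, 12)) for (F in list(0, rational(2, 3))) {
    base <- fSynL(syntheticIC(m, F, l = 1))
    for (l in c(2, 4, 10))
      expect_true(fSynL(syntheticIC(m, F, l)) == base / l)
  }
})

test_that("closed form equals term-by-term summation over all matings", {
  # brute force: g complete groups plus every distinct-leftover subset,
  # averaging progenyIC over all m^2 ordered pairs
  for (m in 1:9) for (F in list(0, 0.5, 1)) {
    expect_true(perLineValue(syntheticIC(m, F)) == bruteForcePerLine(m, F))
  }
})

test_that("invalid parameters are rejected", {
  expect_error(syntheticIC(0, 0), ">= 1")
  expect_error(syntheticIC(4, 2), "F must lie")
  expect_error(syntheticIC(4, 0, l = 0), "l must")
})
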