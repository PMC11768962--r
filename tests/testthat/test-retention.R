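# Genotype-retention probabilities: partition enumeration, distinct
# permutations, exact multinomial masses, and the inclusion-exclusion
# cross-check.

ga4 <- selfedLineArray()
ga3 <- collapseToGA3(ga4)

test_that("frequency sets enumerate partitions into positive parts", {
  fs6 <- enumerateFrequencySets(6, 3)
  expect_length(fs6, 3)
  keys <- vapply(fs6, paste, character(1), collapse = ",")
  expect_setequal(keys, c("1,2,3", "1,1,4", "2,2,2"))
  expect_length(enumerateFrequencySets(15, 3), 19)
  fs12 <- enumerateFrequencySets(12, 3)
  expect_length(fs12, 12)
  nDistinct <- vapply(fs12, function(x) length(unique(x)), integer(1))
  expect_equal(sum(nDistinct == 3), 7)   # seven sets of three different counts
  expect_equal(sum(nDistinct == 2), 4)
  expect_equal(sum(nDistinct == 1), 1)   # {4,4,4}
  # canonical nondecreasing storage
  for (fs in fs12) expect_true(all(diff(fs) >= 0))
  expect_error(enumerateFrequencySets(2, 3), "impossible")
})

test_that("distinct permutation counts follow the multiplicity formula", {
  expect_equal(ndp(c(1, 2, 3)), 6L)
  expect_equal(ndp(c(1, 1, 4)), 3L)
  expect_equal(ndp(c(2, 2, 2)), 1L)
  expect_equal(ndp(c(3, 4, 4, 4)), 4L)
  expect_equal(ndp(c(3, 3, 4, 5)), 12L)
  expect_equal(ndp(c(1, 2, 3, 4)), 24L)
})

test_that("permutation counts add up to the composition count", {
  for (arity in c(3L, 4L)) for (m in arity:16) {
    tot <- sum(vapply(enumerateFrequencySets(m, arity), ndp, integer(1)))
    expect_equal(tot, choose(m - 1, arity - 1))
  }
})

test_that("multinomial masses are exact", {
  expect_true(multinomialMass(c(2, 2, 2), ga3) == rational(90, 1024))
  expect_true(multinomialMass(c(6, 0, 0), ga3) == rational(1, 4)^6)
  # the two heterozygote-heavy permutations of {1,1,12,1} share one tiny mass
  m1 <- multinomialMass(c(1, 1, 12, 1), ga4)
  m2 <- multinomialMass(c(1, 1, 1, 12), ga4)
  expect_true(m1 == m2)
  expect_true(m1 == rational(15 * 14 * 13, 1) / rational(4)^15)
  expect_equal(asNumeric(m1), 2.5e-6, tolerance = 0.02)
  expect_error(multinomialMass(c(1, 2), ga3), "per genotype class")
  expect_error(multinomialMass(c(-1, 4, 3), ga3), "nonnegative")
})

test_that("mass sums over all count vectors are complete", {
  for (m in 1:20) {
    for (ga in list(ga4, ga3)) {
      k <- arity(ga)
      tot <- rational(0)
      if (k == 3L) {
        for (a in 0:m) for (b in 0:(m - a))
          tot <- tot + multinomialMass(c(a, b, m - a - b), ga)
      } else {
        for (a in 0:m) for (b in 0:(m - a)) for (cc in 0:(m - a - b))
          tot <- tot + multinomialMass(c(a, b, cc, m - a - b - cc), ga)
      }
      expect_true(tot == 1)
    }
  }
})

test_that("inclusion probabilities match the reference values", {
  expect_equal(ratRound(inclusionProbability(15, ga4), 4), 0.9467)
  expect_true(inclusionProbability(3, ga3) == rational(3, 16))   # 0.1875
  expect_true(inclusionProbability(3, ga4) == 0)   # four classes cannot fit in 3
  expect_true(inclusionProbability(4, ga4) == rational(3, 32))   # 4!/4^4
})

test_that("enumeration agrees with full brute-force sampling at small m", {
  for (arity in c(3L, 4L)) {
    ga <- if (arity == 4L) ga4 else ga3
    for (m in arity:7) {
      num <- bruteForceInclusionNum(m, arity)
      expect_true(inclusionProbability(m, ga) == rational(num) / rational(4)^m)
    }
  }
})

test_that("enumeration equals inclusion-exclusion exactly up to m = 30", {
  for (ga in list(ga4, ga3)) {
    for (m in arity(ga):30) {
      expect_true(inclusionProbability(m, ga) == inclusionClosedForm(m, ga))
    }
    # below the arity the closed form also collapses to zero
    expect_true(inclusionClosedForm(arity(ga) - 1L, ga) == 0)
  }
})

test_that("the collapsed array dominates and both grow with m", {
  prev4 <- rational(0); prev3 <- rational(0)
  for (m in 1:24) {
    p4 <- inclusionProbability(m, ga4)
    p3 <- inclusionProbability(m, ga3)
    expect_true(p3 >= p4)
    expect_true(p4 >= prev4)
    expect_true(p3 >= prev3)
    prev4 <- p4; prev3 <- p3
  }
  # strictly greater once both are positive
  expect_true(inclusionProbability(6, ga3) > inclusionProbability(6, ga4))
})

test_that("set joint probabilities reproduce the worked size-15 cases", {
  # 756756/2^25 = 0.0225532...; the reference table truncates this cell
  expect_equal(ratTruncate(setJointProbability(15, c(5, 5, 5), ga3), 4), 0.0225)
  expect_equal(ratRound(setJointProbability(15, c(4, 5, 6), ga3), 4), 0.1316)
  expect_equal(ratRound(setJointProbability(15, c(1, 1, 13), ga3), 4), 0.0016)
  expect_equal(ratRound(setJointProbability(15, c(3, 4, 4, 4), ga4), 4), 0.0587)
  expect_equal(ratTruncate(setJointProbability(15, c(3, 3, 4, 5), ga4), 6),
               0.140956)
  # for the equiprobable array the joint value is ndp times one mass
  expect_true(setJointProbability(15, c(3, 4, 4, 4), ga4) ==
              multinomialMass(c(3, 4, 4, 4), ga4) * 4)
  expect_true(setJointProbability(15, c(3, 3, 4, 5), ga4) ==
              multinomialMass(c(3, 3, 4, 5), ga4) * 12)
  expect_error(setJointProbability(14, c(5, 5, 5), ga3), "sum to m")
  expect_error(setJointProbability(15, c(5, 5, 5), ga4), "arity")
})

test_that("the breakdown mirrors the size-6 worked table", {
  bd <- inclusionBreakdown(6, ga3)
  perm <- breakdownTable(bd, level = "permutation", digits = 3)
  key <- function(a, b, cc) perm$prob[perm$A1A1 == a & perm$A1A2 == b & perm$A2A2 == cc]
  expect_equal(key(1, 2, 3), 0.059)
  expect_equal(key(1, 3, 2), 0.117)
  expect_equal(key(2, 1, 3), 0.029)
  expect_equal(key(2, 3, 1), 0.117)
  expect_equal(key(3, 1, 2), 0.029)
  expect_equal(key(3, 2, 1), 0.059)
  expect_equal(key(1, 1, 4), 0.015)
  expect_equal(key(2, 2, 2), 0.088)
  sets <- breakdownTable(bd, level = "set")
  expect_equal(nrow(sets), 3)
  expect_equal(sum(sets$ndp), choose(5, 2))
})

test_that("breakdown totals are internally consistent", {
  for (case in list(list(6, ga3), list(15, ga3), list(10, ga4))) {
    bd <- inclusionBreakdown(case[[1]], case[[2]])
    expect_true(grandTotal(bd) == inclusionProbability(case[[1]], case[[2]]))
    setSum <- Reduce(`+`, bd@setTotals)
    expect_true(setSum == grandTotal(bd))
    for (k in seq_along(bd@sets)) {
      permSum <- Reduce(`+`, lapply(bd@perms[[k]], `[[`, "prob"))
      expect_true(permSum == bd@setTotals[[k]])
      expect_equal(length(bd@perms[[k]]), bd@ndps[k])
    }
  }
  expect_error(inclusionBreakdown(3, ga4), "include them all")
})
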