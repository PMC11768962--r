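# Genotypic arrays and identity-by-descent coefficients of one line's
# selfed progeny.

test_that("selfing a heterozygous line gives four equiprobable genotypes", {
  ga <- selfedLineArray()
  expect_equal(arity(ga), 4L)
  expect_equal(genotypeLabels(ga), c("A1A1", "A1A2", "A2A1", "A2A2"))
  probs <- genotypeProbs(ga)
  for (p in probs) expect_true(p == rational(1, 4))
  expect_true(Reduce(`+`, probs) == 1)
})

test_that("collapsing merges only the heterozygotes", {
  ga3 <- collapseToGA3(selfedLineArray())
  expect_equal(arity(ga3), 3L)
  expect_equal(genotypeLabels(ga3), c("A1A1", "A1A2", "A2A2"))
  probs <- genotypeProbs(ga3)
  expect_true(probs$A1A1 == rational(1, 4))
  expect_true(probs$A1A2 == rational(1, 2))
  expect_true(probs$A2A2 == rational(1, 4))
  expect_true(Reduce(`+`, probs) == 1)
  expect_error(collapseToGA3(ga3), "four-class")
})

test_that("progeny inbreeding coefficients match the per-mating rules", {
  cases <- list(
    list("A1A1", "A1A1", 0,   rational(1)),        # selfing a homozygote
    list("A2A2", "A2A2", 0.5, rational(1)),
    list("A1A1", "A2A2", 0,   rational(0)),        # opposite homozygotes -> F
    list("A1A1", "A2A2", 0.5, rational(1, 2)),
    list("A1A2", "A1A2", 0,   rational(1, 2)),     # selfing the heterozygote
    list("A1A2", "A2A1", 0,   rational(1, 2)),     # het x het cross
    list("A1A1", "A1A2", 0.5, rational(3, 4)),
    list("A2A1", "A2A2", 1,   rational(1)))
  for (cs in cases)
    expect_true(progenyIC(cs[[1]], cs[[2]], cs[[3]]) == cs[[4]])
  # reciprocal crosses have identical coefficients
  for (F in c(0, 0.5, 1))
    for (p1 in c("A1A1", "A1A2", "A2A1", "A2A2"))
      for (p2 in c("A1A1", "A1A2", "A2A1", "A2A2"))
        expect_true(progenyIC(p1, p2, F) == progenyIC(p2, p1, F))
  expect_error(progenyIC("A1A1", "A1A1", 1.5), "F must lie")
  expect_error(progenyIC("A1A1", "A1A1", -0.1), "F must lie")
})

test_that("group averages equal direct summation of the mating table", {
  labs <- c("A1A1", "A1A2", "A2A1", "A2A2")
  for (F in list(0, rational(1, 4), 0.5, rational(3, 4), 1,
                 rational(1, 3))) {
    # four selfings
    selfSum <- Reduce(`+`, lapply(labs, function(g) progenyIC(g, g, F)))
    expect_true(selfSum / 4 == meanSelfingIC(F))
    # twelve ordered within-group crosses
    crossSum <- rational(0)
    for (i in 1:4) for (j in 1:4) if (i != j)
      crossSum <- crossSum + progenyIC(labs[i], labs[j], F)
    expect_true(crossSum / 12 == meanWithinGroupCrossIC(F))
    # all sixteen ordered pairs: the global mean (1+F)/2
    expect_true((selfSum + crossSum) / 16 == meanBetweenGroupIC(F))
  }
})

test_that("closed-form averages take their known values", {
  expect_equal(asNumeric(meanSelfingIC(0)), 0.75)
  expect_true(meanWithinGroupCrossIC(0) == rational(5, 12))
  expect_equal(asNumeric(meanBetweenGroupIC(0)), 0.5)
  expect_true(meanSelfingIC(1) == 1 && meanWithinGroupCrossIC(1) == 1 &&
              meanBetweenGroupIC(1) == 1)
  expect_true(meanSelfingIC(0.5) == rational(7, 8))
  expect_true(meanWithinGroupCrossIC(0.5) == rational(17, 24))
  expect_true(meanBetweenGroupIC(0.5) == rational(3, 4))
})

test_that("average ordering holds across the whole F range", {
  for (F in list(0, rational(1, 8), 0.5, rational(9, 10), 1)) {
    expect_true(meanSelfingIC(F) >= meanBetweenGroupIC(F))
    expect_true(meanBetweenGroupIC(F) >= meanWithinGroupCrossIC(F))
  }
})

test_that("the mating table is symmetric with all means (1+F)/2", {
  tab <- matingICTable()
  for (g in c("A1A1", "A1A2", "A2A1", "A2A2")) {
    rm <- rowMeanIC(tab, g)
    expect_true(rm@a == rational(1, 2) && rm@b == rational(1, 2))
  }
  gm <- grandMeanIC(tab)
  for (F in c(0, 0.25, 1))
    expect_true(icFormEval(gm, F) == meanBetweenGroupIC(F))
})
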