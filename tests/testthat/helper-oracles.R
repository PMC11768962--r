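# Independent brute-force oracles, deliberately built on plain base-R integer
# arithmetic (exact for the small m used here: every count stays far below
# 2^53) rather than on the package's enumeration machinery.

# all ordered samples of size m over `arity` categories, as a matrix
.allOrderedSamples <- function(m, arity) {
  as.matrix(expand.grid(rep(list(seq_len(arity)), m)))
}

# weight of one category in "numerator over 4^m" units: GA4 -> 1 each,
# GA3 -> c(1, 2, 1)
.oracleWeights <- function(arity) if (arity == 4L) c(1, 1, 1, 1) else c(1, 2, 1)

# P(all categories present) as numerator over 4^m, by full enumeration
bruteForceInclusionNum <- function(m, arity) {
  grid <- .allOrderedSamples(m, arity)
  w <- .oracleWeights(arity)
  tot <- 0
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    if (length(unique(row)) == arity) tot <- tot + prod(w[row])
  }
  tot
}

# P(equal A1/A2 allele counts) as numerator over 4^m; categories are the four
# ordered genotypes with A1-allele contributions 2, 1, 1, 0
bruteForceEqualFreqNum <- function(m) {
  contrib <- c(2, 1, 1, 0)
  grid <- .allOrderedSamples(m, 4L)
  sum(apply(grid, 1, function(row) sum(contrib[row]) == m))
}

# per-line inbreeding value by direct summation: plants are g complete groups
# holding all four genotypes plus e leftovers forming every possible distinct
# subset (averaged); matings are all m^2 ordered pairs, selfing on i == j.
# Individual mating coefficients come from progenyIC(), which is pinned to
# its defining table elsewhere, so this is a second, term-by-term route to
# the closed-form value.
bruteForcePerLine <- function(m, F) {
  d <- decomposeSample(m)
  g <- nGroups(d); e <- nLeftover(d)
  labs <- c("A1A1", "A1A2", "A2A1", "A2A2")
  groupPart <- rep(seq_len(4), times = g)
  leftoverSets <- if (e > 0) utils::combn(4, e, simplify = FALSE) else list(integer(0))
  total <- rational(0)
  for (lo in leftoverSets) {
    genos <- labs[c(groupPart, lo)]
    for (i in seq_len(m)) for (j in seq_len(m))
      total <- total + progenyIC(genos[i], genos[j], F)
  }
  total / (length(leftoverSets) * m^2)
}
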