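# Genotype-retention probabilities by exact enumeration.
#
# The probability that a random sample of m plants includes every genotype of
# a genotypic array is built exactly as a sum over the integer partitions of m
# into `arity` positive parts (the frequency sets), expanded into the distinct
# permutations of each set (the ordered assignments of counts to labelled
# genotypes), each weighted by its multinomial mass.  An inclusion-exclusion
# closed form over genotype subsets provides an independent route to the same
# rational, used as a cross-check throughout the tests.
#
# Every mass is an integer over L^m where L is the least common multiple of
# the genotype-probability denominators (L = 4 for both canonical arrays), so
# sums accumulate exact integer numerators and reduce once at the end.

# partitions of m into exactly k parts, each >= minPart, nondecreasing order
.partitionsExact <- function(m, k, minPart = 1L) {
  if (k == 1L) {
    if (m >= minPart) return(list(m))
    return(list())
  }
  out <- list()
  for (first in seq.int(minPart, m %/% k, length.out = max(0L, m %/% k - minPart + 1L))) {
    for (rest in .partitionsExact(m - first, k - 1L, first))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}

#' Enumerate the frequency sets of a sample
#'
#' A frequency set is an unordered multiset of positive genotype counts
#' summing to m, one count per genotype class: an integer partition of m into
#' exactly `arity` positive parts.  These are the sets over which the
#' inclusion probability is assembled.
#'
#' @param m sample size, integer >= `arity`.
#' @param arity number of genotype classes, 3 or 4.
#' @return List of integer vectors in nondecreasing (canonical) order.
#' @examples
#' enumerateFrequencySets(6, 3)   # {1,2,3}, {1,1,4}, {2,2,2}
#' length(enumerateFrequencySets(15, 3))  # 19
#' @export
enumerateFrequencySets <- function(m, arity) {
  arity <- as.integer(arity)
  if (!arity %in% c(3L, 4L)) stop("arity must be 3 or 4")
  if (length(m) != 1L || m != floor(m)) stop("m must be a single integer")
  if (m < arity)
    stop("no frequency set exists: m < arity, inclusion of all genotypes is impossible")
  lapply(.partitionsExact(as.integer(m), arity), as.integer)
}

#' Number of distinct permutations of a frequency set
#'
#' The number of distinct ordered assignments of the multiset of counts to
#' the labelled genotypes: arity! divided by the product of factorials of the
#' multiplicities of repeated counts.
#'
#' @param fs integer vector of positive counts (a frequency set).
#' @return integer.
#' @examples
#' ndp(c(1, 2, 3))  # 6
#' ndp(c(1, 1, 4))  # 3
#' ndp(c(2, 2, 2))  # 1
#' @export
ndp <- function(fs) {
  if (any(fs < 1) || any(fs != floor(fs))) stop("frequency sets hold positive integers")
  mult <- table(fs)
  as.integer(factorial(length(fs)) / prod(factorial(mult)))
}

# all distinct permutations of a count vector, lexicographic order
.distinctPerms <- function(counts) {
  # recursive expansion, choosing each distinct remaining value in order
  expand <- function(prefix, remaining) {
    if (length(remaining) == 0L) return(list(prefix))
    out <- list()
    for (v in unique(remaining)) {
      idx <- match(v, remaining)
      for (p in expand(c(prefix, v), remaining[-idx]))
        out[[length(out) + 1L]] <- p
    }
    out
  }
  expand(integer(0), sort(counts))
}

# scaled representation of an array: every mass is an integer over L^m
.gaScale <- function(ga) {
  probs <- .gaProbs(ga)
  dens <- vapply(probs, function(p) .bnToNum(p$d), numeric(1))
  nums <- vapply(probs, function(p) p$s * .bnToNum(p$n), numeric(1))
  if (any(dens > 2^40)) stop("array probabilities too fine-grained")
  L <- Reduce(function(a, b) a * b / .gcdSmall(a, b), dens)
  list(L = L, w = nums * (L / dens))
}

.gcdSmall <- function(a, b) {
  while (b != 0) { t <- a %% b; a <- b; b <- t }
  a
}

# exact multinomial coefficient m!/(prod counts!) as a bignat
.bnMultiCoef <- function(m, counts) {
  q <- .bnFactorial(m)
  for (f in counts) {
    if (f > 1) {
      dm <- .bnDivMod(q, .bnFactorial(f))
      if (!.bnIsZero(dm$r)) stop("internal error: non-integer multinomial coefficient")
      q <- dm$q
    }
  }
  q
}

# integer numerator of one multinomial mass over denominator L^m
.massNum <- function(counts, w) {
  m <- sum(counts)
  num <- .bnMultiCoef(m, counts)
  for (q in seq_along(counts)) {
    if (counts[q] == 0L) next
    if (w[q] == 0) return(0)
    num <- .bnMul(num, .bnPow(.bnFromNum(w[q]), counts[q]))
  }
  num
}

#' Exact multinomial mass of an ordered count vector
#'
#' The probability that a multinomial sample of size `sum(counts)` from the
#' array's genotype probabilities realises exactly these counts, in the
#' array's genotype order.  Zero counts are allowed.
#'
#' @param counts nonnegative integer vector aligned to `genotypeLabels(ga)`.
#' @param ga a [GenotypicArray].
#' @return A [Rational].
#' @examples
#' ga3 <- collapseToGA3(selfedLineArray())
#' multinomialMass(c(2, 2, 2), ga3)        # 90/1024
#' @export
multinomialMass <- function(counts, ga) {
  stopifnot(is(ga, "GenotypicArray"))
  if (length(counts) != ga@arity)
    stop("counts must have one entry per genotype class of the array")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be nonnegative integers")
  sc <- .gaScale(ga)
  m <- sum(counts)
  .R(.rMake(1L, .massNum(as.integer(counts), sc$w), .bnPow(.bnFromNum(sc$L), m)))
}

#' Probability that a sample includes every genotype of the array
#'
#' Assembled by enumerating all frequency sets of m (partitions into `arity`
#' positive parts), expanding each into its distinct permutations and summing
#' the exact multinomial masses.  For m below the arity the probability is
#' zero.  [inclusionClosedForm()] computes the same quantity independently by
#' inclusion-exclusion; the two agree as exact rationals.
#'
#' @param m sample size, integer >= 1.
#' @param ga a [GenotypicArray].
#' @return A [Rational].
#' @examples
#' ga3 <- collapseToGA3(selfedLineArray())
#' asNumeric(inclusionProbability(3, ga3))            # 0.1875
#' ratRound(inclusionProbability(15, selfedLineArray()), 4)  # 0.9467
#' @export
inclusionProbability <- function(m, ga) {
  stopifnot(is(ga, "GenotypicArray"))
  if (length(m) != 1L || m != floor(m) || m < 1) stop("m must be a single integer >= 1")
  if (m < ga@arity) return(rational(0))
  sc <- .gaScale(ga)
  equalWeights <- length(unique(sc$w)) == 1L
  tot <- 0
  for (fs in enumerateFrequencySets(m, ga@arity)) {
    if (equalWeights) {
      tot <- .bnAdd(tot, .bnMulSmall(.massNum(fs, sc$w), ndp(fs)))
    } else {
      for (perm in .distinctPerms(fs))
        tot <- .bnAdd(tot, .massNum(perm, sc$w))
    }
  }
  .R(.rMake(1L, tot, .bnPow(.bnFromNum(sc$L), m)))
}

#' Inclusion probability by inclusion-exclusion
#'
#' Independent closed form for the probability that all genotype classes are
#' represented: the sum over genotype subsets S of (-1)^|S| (1 - P(S))^m.
#' Used to cross-check the enumeration route exactly.
#'
#' @inheritParams inclusionProbability
#' @return A [Rational].
#' @examples
#' ga3 <- collapseToGA3(selfedLineArray())
#' inclusionClosedForm(3, ga3) == inclusionProbability(3, ga3)  # TRUE
#' @export
inclusionClosedForm <- function(m, ga) {
  stopifnot(is(ga, "GenotypicArray"))
  if (length(m) != 1L || m != floor(m) || m < 1) stop("m must be a single integer >= 1")
  probs <- .gaProbs(ga)
  k <- ga@arity
  acc <- .rZero
  for (S in 0:(2^k - 1L)) {
    psum <- .rZero
    bits <- 0L
    for (q in seq_len(k)) {
      if (bitwAnd(S, bitwShiftL(1L, q - 1L)) != 0L) {
        psum <- .rAdd(psum, probs[[q]])
        bits <- bits + 1L
      }
    }
    term <- .rPowInt(.rSub(.rOne, psum), m)
    if (bits %% 2L == 1L) term <- .rNeg(term)
    acc <- .rAdd(acc, term)
  }
  .R(acc)
}

#' Joint probability of one frequency set over all its distinct permutations
#'
#' The contribution of a single frequency set to the probability that no
#' genotype is lost: the sum of the multinomial masses of all distinct
#' ordered assignments of its counts to the genotypes.  When the array's
#' probabilities are all equal every permutation has the same mass and the
#' sum collapses to ndp times one mass.
#'
#' @param m sample size.
#' @param fs integer vector of positive counts summing to m (any order).
#' @param ga a [GenotypicArray].
#' @return A [Rational].
#' @examples
#' ratRound(setJointProbability(15, c(4, 5, 6),
#'          collapseToGA3(selfedLineArray())), 4)   # 0.1316
#' ratRound(setJointProbability(15, c(3, 4, 4, 4), selfedLineArray()), 4)  # 0.0587
#' @export
setJointProbability <- function(m, fs, ga) {
  stopifnot(is(ga, "GenotypicArray"))
  if (length(fs) != ga@arity) stop("frequency set size must match the array's arity")
  if (any(fs < 1) || any(fs != floor(fs))) stop("frequency sets hold positive integers")
  if (sum(fs) != m) stop("frequency set must sum to m")
  sc <- .gaScale(ga)
  fs <- sort(as.integer(fs))
  tot <- 0
  if (length(unique(sc$w)) == 1L) {
    tot <- .bnMulSmall(.massNum(fs, sc$w), ndp(fs))
  } else {
    for (perm in .distinctPerms(fs)) tot <- .bnAdd(tot, .massNum(perm, sc$w))
  }
  .R(.rMake(1L, tot, .bnPow(.bnFromNum(sc$L), m)))
}

#' Full per-set, per-permutation breakdown of the inclusion probability
#'
#' Mirrors the tabular construction of the inclusion probability: one row per
#' frequency set with its distinct permutations, each permutation's exact
#' mass, the set total, and the grand total over all sets.
#'
#' @slot m sample size.
#' @slot arity number of genotype classes.
#' @slot labels genotype labels of the array.
#' @slot sets list of canonical frequency sets (integer vectors).
#' @slot ndps integer vector of distinct-permutation counts per set.
#' @slot perms list (per set) of lists with elements `counts` and `prob`.
#' @slot setTotals list of [Rational] per-set totals.
#' @slot grandTotal [Rational], equal to [inclusionProbability()].
#' @seealso [inclusionBreakdown()], [breakdownTable()]
#' @exportClass InclusionBreakdown
setClass("InclusionBreakdown",
         representation(m = "integer", arity = "integer", labels = "character",
                        sets = "list", ndps = "integer", perms = "list",
                        setTotals = "list", grandTotal = "Rational"))

#' Compute the inclusion-probability breakdown
#'
#' @param m sample size, integer >= `arity` of the array.
#' @param ga a [GenotypicArray].
#' @return An [InclusionBreakdown].
#' @examples
#' bd <- inclusionBreakdown(6, collapseToGA3(selfedLineArray()))
#' breakdownTable(bd)
#' @export
inclusionBreakdown <- function(m, ga) {
  stopifnot(is(ga, "GenotypicArray"))
  if (length(m) != 1L || m != floor(m) || m < 1) stop("m must be a single integer >= 1")
  if (m < ga@arity)
    stop("m below the number of genotype classes: no sample can include them all")
  sc <- .gaScale(ga)
  den <- .bnPow(.bnFromNum(sc$L), m)
  sets <- enumerateFrequencySets(m, ga@arity)
  ndps <- vapply(sets, ndp, integer(1))
  permsOut <- vector("list", length(sets))
  setTotals <- vector("list", length(sets))
  grand <- 0
  for (k in seq_along(sets)) {
    ps <- .distinctPerms(sets[[k]])
    rows <- vector("list", length(ps))
    setTot <- 0
    for (i in seq_along(ps)) {
      num <- .massNum(ps[[i]], sc$w)
      rows[[i]] <- list(counts = ps[[i]], prob = .R(.rMake(1L, num, den)))
      setTot <- .bnAdd(setTot, num)
    }
    permsOut[[k]] <- rows
    setTotals[[k]] <- .R(.rMake(1L, setTot, den))
    grand <- .bnAdd(grand, setTot)
  }
  new("InclusionBreakdown", m = as.integer(m), arity = ga@arity,
      labels = ga@labels, sets = sets, ndps = ndps, perms = permsOut,
      setTotals = setTotals, grandTotal = .R(.rMake(1L, grand, den)))
}

#' Grand total of an inclusion breakdown
#' @param x an [InclusionBreakdown].
#' @return A [Rational].
#' @export
grandTotal <- function(x) {
  stopifnot(is(x, "InclusionBreakdown"))
  x@grandTotal
}

#' Tabulate an inclusion breakdown
#'
#' @param x an [InclusionBreakdown].
#' @param level `"set"` for one row per frequency set (counts, ndp, set
#'   total) or `"permutation"` for one row per distinct permutation.
#' @param digits decimal places (half-away-from-zero) for the probability
#'   column.
#' @return A data.frame.
#' @export
breakdownTable <- function(x, level = c("set", "permutation"), digits = 4) {
  stopifnot(is(x, "InclusionBreakdown"))
  level <- match.arg(level)
  cn <- x@labels
  if (level == "set") {
    counts <- do.call(rbind, x@sets)
    df <- data.frame(k = seq_along(x@sets))
    for (j in seq_len(x@arity)) df[[cn[j]]] <- counts[, j]
    df$ndp <- x@ndps
    df$setTotal <- vapply(x@setTotals, ratRound, numeric(1), digits = digits)
    return(df)
  }
  rows <- list()
  for (k in seq_along(x@sets)) {
    for (i in seq_along(x@perms[[k]])) {
      p <- x@perms[[k]][[i]]
      rec <- c(list(k = k, i = i), as.list(p$counts),
               list(prob = ratRound(p$prob, digits)))
      names(rec) <- c("k", "i", cn, "prob")
      rows[[length(rows) + 1L]] <- as.data.frame(rec)
    }
  }
  do.call(rbind, rows)
}

#' @export
setMethod("show", "InclusionBreakdown", function(object) {
  cat("InclusionBreakdown: m = ", object@m, ", ", object@arity,
      " genotype classes, ", length(object@sets), " frequency sets\n", sep = "")
  print(utils::head(breakdownTable(object), 8))
  if (length(object@sets) > 8) cat("  ...\n")
  cat("grand total = ", .rToChar(.ri(object@grandTotal)),
      " (", format(.rToNum(.ri(object@grandTotal)), digits = 6), ")\n", sep = "")
})
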