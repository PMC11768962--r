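# Allele-level statistics of a founder sample: the probability of losing an
# allele outright, the probability that the sample preserves the line's equal
# allele frequencies, and the inbreeding coefficient of the progeny array
# implied by an arbitrary sample.

#' Probability of losing an allele from the sample
#'
#' An allele is lost only when all m plants are A1A1 or all are A2A2, which
#' happens with probability 2*(1/4)^m regardless of whether the four-class or
#' the collapsed array is used.  Loss drives the sample's inbreeding
#' coefficient to its maximum of 1.
#'
#' @param m sample size, integer >= 1.
#' @return A [Rational].
#' @examples
#' asNumeric(geneLossProbability(1))        # 0.5
#' ratTruncate(geneLossProbability(5), 4)   # 0.0019
#' @export
geneLossProbability <- function(m) {
  if (length(m) != 1L || m != floor(m) || m < 1) stop("m must be a single integer >= 1")
  .R(.rMake(1L, .bnFromNum(2), .bnPow(.bnFromNum(4), m)))
}

#' Probability that the sample preserves equal allele frequencies
#'
#' The probability that a multinomial sample of m genotypes from the
#' four-class selfed-line array carries exactly m copies of A1 (and hence m
#' of A2), computed by exact enumeration over all genotype count vectors
#' (a, b, c, d) with 2a + b + c = m.  Because the 2m genes of the sample are
#' independent fair draws this equals choose(2m, m)/4^m, which
#' [equalAlleleFreqClosedForm()] computes independently.  The probability is
#' strictly decreasing in m and tends to zero.
#'
#' @param m sample size, integer >= 1.
#' @return A [Rational].
#' @examples
#' asNumeric(equalAlleleFreqProbability(2))  # 0.375
#' asNumeric(equalAlleleFreqProbability(3))  # 0.3125
#' @export
equalAlleleFreqProbability <- function(m) {
  if (length(m) != 1L || m != floor(m) || m < 1) stop("m must be a single integer >= 1")
  m <- as.integer(m)
  sc <- .gaScale(selfedLineArray())
  tot <- 0
  for (a in 0:(m %/% 2L)) {
    # 2a + b + c = m with b + c <= m - a; d = m - a - b - c
    for (b in 0:(m - 2L * a)) {
      cc <- m - 2L * a - b
      d <- m - a - b - cc
      if (d < 0L) next
      tot <- .bnAdd(tot, .massNum(c(a, b, cc, d), sc$w))
    }
  }
  .R(.rMake(1L, tot, .bnPow(.bnFromNum(sc$L), m)))
}

#' Closed form for the equal-allele-frequency probability
#'
#' The 2m genes of the sample are independent draws of A1 or A2 with
#' probability 1/2 each, so equal frequencies occur with probability
#' choose(2m, m)/2^(2m).  Serves as the independent oracle for
#' [equalAlleleFreqProbability()].
#'
#' @inheritParams equalAlleleFreqProbability
#' @return A [Rational].
#' @export
equalAlleleFreqClosedForm <- function(m) {
  if (length(m) != 1L || m != floor(m) || m < 1) stop("m must be a single integer >= 1")
  num <- .bnMultiCoef(2L * m, c(m, m))
  .R(.rMake(1L, num, .bnPow(.bnFromNum(4), m)))
}

#' Inbreeding coefficient of the progeny implied by a sample
#'
#' For a sample with A1 allele frequency p (and q = 1 - p), one round of
#' random mating of the sampled plants produces the Hardy-Weinberg progeny
#' array p^2, pq, qp, q^2, whose inbreeding coefficient is the linear form
#' (p^2 + q^2) + 2pq*F.  The intercept is minimised at 1/2 exactly when
#' p = q = 1/2; a monomorphic sample gives coefficient 1 (fixation).
#'
#' @slot a intercept p^2 + q^2, a [Rational].
#' @slot b slope 2pq on F, a [Rational].
#' @slot p,q sample allele frequencies of A1 and A2, [Rational].
#' @seealso [progenyICFromSample()]
#' @exportClass ProgenyIC
setClass("ProgenyIC",
         representation(a = "Rational", b = "Rational", p = "Rational", q = "Rational"),
         validity = function(object) {
  one <- .rAdd(.ri(object@p), .ri(object@q))
  if (.rCmp(one, .rOne) != 0L) return("p + q must equal 1")
  if (.rCmp(.rAdd(.ri(object@a), .ri(object@b)), .rOne) != 0L)
    return("a + b must equal 1")
  half <- .rMake(1L, 1, 2)
  if (.rCmp(.ri(object@a), half) < 0L) return("intercept below 1/2 is impossible")
  TRUE
})

#' @export
setMethod("show", "ProgenyIC", function(object) {
  cat("Progeny inbreeding coefficient: ",
      .rToChar(.ri(object@a)), " + ", .rToChar(.ri(object@b)), "*F",
      "   (p = ", .rToChar(.ri(object@p)), ")\n", sep = "")
})

#' Accessors for a progeny inbreeding form
#' @param x a [ProgenyIC].
#' @return A [Rational].
#' @export
icIntercept <- function(x) { stopifnot(is(x, "ProgenyIC")); x@a }

#' @rdname icIntercept
#' @export
icSlope <- function(x) { stopifnot(is(x, "ProgenyIC")); x@b }

#' @rdname icIntercept
#' @export
alleleFreqA1 <- function(x) { stopifnot(is(x, "ProgenyIC")); x@p }

#' Progeny inbreeding coefficient from sample genotype counts
#'
#' @param counts nonnegative integer vector of length 4: counts of A1A1,
#'   A1A2, A2A1 and A2A2 in the sample; must sum to at least 1.
#' @return A [ProgenyIC]; evaluate it at a given F with [icFormValue()].
#' @examples
#' progenyICFromSample(c(1, 1, 12, 1))   # 1/2 + 1/2 F
#' progenyICFromSample(c(1, 1, 1, 12))   # 173/225 + 52/225 F, i.e. 0.77 + 0.23 F
#' @export
progenyICFromSample <- function(counts) {
  if (length(counts) != 4L || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be four nonnegative integers (A1A1, A1A2, A2A1, A2A2)")
  m <- sum(counts)
  if (m < 1) stop("the sample must contain at least one plant")
  p <- .rMake(1L, .bnFromNum(2 * counts[1] + counts[2] + counts[3]),
              .bnFromNum(2 * m))
  q <- .rSub(.rOne, p)
  a <- .rAdd(.rMul(p, p), .rMul(q, q))
  b <- .rMul(.rMul(.rFromInt(2), p), q)
  out <- new("ProgenyIC", a = .R(a), b = .R(b), p = .R(p), q = .R(q))
  out
}

#' Evaluate a progeny inbreeding form at a given F
#' @param x a [ProgenyIC].
#' @param F parental inbreeding coefficient in \[0, 1\].
#' @return A [Rational] equal to a + b*F.
#' @export
icFormValue <- function(x, F) {
  stopifnot(is(x, "ProgenyIC"))
  f <- .checkF(F)
  .R(.rAdd(.ri(x@a), .rMul(.ri(x@b), f)))
}
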