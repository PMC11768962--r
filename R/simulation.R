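# Monte Carlo gene-dropping oracle.
#
# Every analytic quantity in the package has a stochastic counterpart here,
# estimated under the model the formulas assume: l unrelated lines of
# inbreeding F, m plants per line, random mating of the m*l plants as
# uniformly chosen ordered pairs (selfing included).
#
# Two sampling schemes are provided for the inbreeding target.  The default
# "grouped" scheme draws each line's sample as g complete four-plant groups
# holding all four selfed-line genotypes plus e leftover plants with distinct
# genotypes, which is the structure the exact formula weights (within-group
# crosses at (5+7F)/12).  The "iid" scheme draws all m genotypes
# independently from the four-class array; it has a different exact value,
# [(3+F)/4 + (m-1)(1+F)/2] / (m l), which the simulator validates instead,
# making the difference between the two sampling readings measurable.
#
# The retention, gene-loss and equal-frequency targets use iid multinomial
# sampling, which is the model their analytic formulas assume.

#' Monte Carlo estimate with its analytic counterpart
#'
#' @slot target character, which statistic was estimated.
#' @slot estimate empirical proportion over replicates.
#' @slot se binomial standard error sqrt(p(1-p)/n).
#' @slot nReps number of replicates.
#' @slot analytic exact value from the corresponding analytic module.
#' @slot z (estimate - analytic)/se; when the empirical se is zero (all
#'   replicates agreed) the binomial standard error at the analytic value is
#'   used instead, and z is 0 when that is also zero and the values agree.
#' @slot seed the RNG seed used (NA if none was set).
#' @exportClass SimResult
setClass("SimResult",
         representation(target = "character", estimate = "numeric",
                        se = "numeric", nReps = "numeric",
                        analytic = "numeric", z = "numeric", seed = "numeric"))

#' @export
setMethod("show", "SimResult", function(object) {
  cat("SimResult [", object@target, "]\n", sep = "")
  cat(sprintf("  estimate = %.6f (SE %.6f, n = %d)\n",
              object@estimate, object@se, as.integer(object@nReps)))
  cat(sprintf("  analytic = %.6f   z = %.3f\n", object@analytic, object@z))
})

#' Accessors for a Monte Carlo result
#' @param x a [SimResult].
#' @return numeric scalar.
#' @export
estimate <- function(x) { stopifnot(is(x, "SimResult")); x@estimate }

#' @rdname estimate
#' @export
standardError <- function(x) { stopifnot(is(x, "SimResult")); x@se }

#' @rdname estimate
#' @export
analyticValue <- function(x) { stopifnot(is(x, "SimResult")); x@analytic }

#' @rdname estimate
#' @export
zScore <- function(x) { stopifnot(is(x, "SimResult")); x@z }

.simResult <- function(target, hits, nReps, analytic, seed) {
  p <- mean(hits)
  se <- sqrt(p * (1 - p) / nReps)
  seRef <- if (se > 0) se else sqrt(analytic * (1 - analytic) / nReps)
  z <- if (seRef > 0) (p - analytic) / seRef else if (p == analytic) 0 else Inf
  new("SimResult", target = target, estimate = p, se = se,
      nReps = nReps, analytic = analytic, z = z,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Draw one multinomial sample of genotypes from the selfed-line array
#'
#' @param m sample size, integer >= 1.
#' @return Named integer vector of counts of A1A1, A1A2, A2A1, A2A2.
#' @examples
#' set.seed(1); simulateSample(15)
#' @export
simulateSample <- function(m) {
  if (length(m) != 1L || m != floor(m) || m < 1) stop("m must be a single integer >= 1")
  counts <- as.integer(stats::rmultinom(1, m, rep(1 / 4, 4)))
  stats::setNames(counts, .GENOTYPES4)
}

# ordered allele pairs of the four genotypes: 1..4 -> (1,1),(1,2),(2,1),(2,2)
.alleleOf <- function(genotype, position) {
  ifelse(position == 1L, ifelse(genotype <= 2L, 1L, 2L),
         ifelse(genotype == 1L | genotype == 3L, 1L, 2L))
}

#' Gene-dropping estimate of the synthetic variety's inbreeding coefficient
#'
#' Per replicate: two parents are chosen uniformly with replacement from the
#' m*l plants; each transmits one uniformly chosen allele; the replicate
#' scores whether the two transmitted alleles are identical by descent.
#' Alleles from different lines are never IBD; within a line the two founder
#' alleles A1 and A2 are IBD with probability F.  Under the default
#' `scheme = "grouped"` each line's plants form complete four-genotype groups
#' plus distinct-genotype leftovers and the IBD frequency estimates the exact
#' F_SynL of [syntheticIC()]; under `scheme = "iid"` all genotypes are
#' independent draws from the array and the estimate targets the iid analytic
#' value [(3+F)/4 + (m-1)(1+F)/2]/(m*l) instead.
#'
#' @param m plants per line.
#' @param F parental inbreeding coefficient in \[0, 1\].
#' @param l number of unrelated lines.
#' @param nReps number of replicates.
#' @param seed optional RNG seed for reproducibility.
#' @param scheme `"grouped"` (matches the exact formula) or `"iid"`.
#' @return A [SimResult].
#' @examples
#' simulateFSyn(4, 0, 1, nReps = 2e4, seed = 7)
#' @export
simulateFSyn <- function(m, F, l = 1L, nReps = 1e5, seed = NULL,
                         scheme = c("grouped", "iid")) {
  scheme <- match.arg(scheme)
  d <- decomposeSample(m)
  if (!is.null(seed)) set.seed(seed)
  fNum <- asNumeric(asRational(F))
  n <- as.integer(nReps)
  if (n < 1L) stop("nReps must be >= 1")

  L1 <- sample.int(l, n, replace = TRUE)
  L2 <- sample.int(l, n, replace = TRUE)
  P1 <- sample.int(m, n, replace = TRUE)
  P2 <- sample.int(m, n, replace = TRUE)
  g1 <- sample.int(4L, n, replace = TRUE)
  g2 <- sample.int(4L, n, replace = TRUE)

  samePlant <- (L1 == L2) & (P1 == P2)
  g2[samePlant] <- g1[samePlant]
  if (scheme == "grouped") {
    # plants 1..4g fill complete groups of four distinct genotypes; the e
    # leftovers (positions 4g+1..m) are a uniform distinct subset, so any two
    # distinct plants of one group form a uniform ordered pair of distinct
    # genotypes, while plants of different groups are independent
    grp1 <- (P1 - 1L) %/% 4L
    grp2 <- (P2 - 1L) %/% 4L
    sameGroup <- (L1 == L2) & (grp1 == grp2) & !samePlant
    k <- sum(sameGroup)
    if (k > 0) {
      shift <- sample.int(3L, k, replace = TRUE)
      g2[sameGroup] <- ((g1[sameGroup] - 1L + shift) %% 4L) + 1L
    }
  }

  pos1 <- sample.int(2L, n, replace = TRUE)
  pos2 <- sample.int(2L, n, replace = TRUE)
  lab1 <- .alleleOf(g1, pos1)
  lab2 <- .alleleOf(g2, pos2)
  ibd <- (L1 == L2) & (lab1 == lab2 | stats::runif(n) < fNum)

  analytic <- if (scheme == "grouped") {
    asNumeric(fSynL(syntheticIC(m, F, l)))
  } else {
    f <- .checkF(F)
    per <- .rAdd(.rDiv(.rAdd(.rFromInt(3), f), .rFromInt(4 * m)),
                 .rMul(.rFromInt(m - 1),
                       .rDiv(.rAdd(.rOne, f), .rFromInt(2 * m))))
    .rToNum(.rDiv(per, .rFromInt(l)))
  }
  .simResult(paste0("f_syn_", scheme), ibd, n, analytic, seed)
}

#' Monte Carlo estimate of one analytic statistic
#'
#' Dispatches to the estimator for the requested target and pairs the
#' empirical proportion with the exact value from the corresponding analytic
#' function: `"inclusion_ga4"` and `"inclusion_ga3"` against
#' [inclusionProbability()], `"gene_loss"` against [geneLossProbability()],
#' `"equal_freq"` against [equalAlleleFreqProbability()], and `"f_syn"`
#' against [syntheticIC()] via [simulateFSyn()].
#'
#' @param target one of `"inclusion_ga4"`, `"inclusion_ga3"`, `"gene_loss"`,
#'   `"equal_freq"`, `"f_syn"`.
#' @param m sample size per line.
#' @param F parental inbreeding coefficient (used by `"f_syn"` only).
#' @param l number of lines (used by `"f_syn"` only).
#' @param nReps number of replicates.
#' @param seed optional RNG seed.
#' @return A [SimResult].
#' @examples
#' simulateStatistic("equal_freq", m = 2, nReps = 2e4, seed = 11)
#' @export
simulateStatistic <- function(target = c("inclusion_ga4", "inclusion_ga3",
                                         "gene_loss", "equal_freq", "f_syn"),
                              m, F = 0, l = 1L, nReps = 1e5, seed = NULL) {
  target <- match.arg(target)
  if (target == "f_syn")
    return(simulateFSyn(m, F, l, nReps = nReps, seed = seed))
  if (length(m) != 1L || m != floor(m) || m < 1) stop("m must be a single integer >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(nReps)
  counts <- stats::rmultinom(n, m, rep(1 / 4, 4))
  hits <- switch(target,
    inclusion_ga4 = colSums(counts >= 1L) == 4L,
    inclusion_ga3 = counts[1L, ] >= 1L & (counts[2L, ] + counts[3L, ]) >= 1L &
                    counts[4L, ] >= 1L,
    gene_loss = counts[1L, ] == m | counts[4L, ] == m,
    equal_freq = (2L * counts[1L, ] + counts[2L, ] + counts[3L, ]) == m)
  analytic <- switch(target,
    inclusion_ga4 = asNumeric(inclusionProbability(m, selfedLineArray())),
    inclusion_ga3 = asNumeric(inclusionProbability(m, collapseToGA3(selfedLineArray()))),
    gene_loss = asNumeric(geneLossProbability(m)),
    equal_freq = asNumeric(equalAlleleFreqProbability(m)))
  .simResult(target, hits, n, analytic, seed)
}
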