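# Inbreeding coefficient of the synthetic variety.
#
# A line's m sampled plants are viewed as g = floor(m/4) complete groups that
# each hold all four selfed-line genotypes, plus e = m mod 4 leftover plants
# carrying distinct genotypes.  Random mating of the m*l plants (ordered
# pairs, selfing included) then gives
#
#   F_SynL = [ m(3+F)/4 + (12g + e(e-1))(5+7F)/12
#              + (16g(g-1) + 8ge)(1+F)/2 ] / (m^2 l)
#
# where the three averages weight the m selfings, the within-group crosses,
# and the between-group crosses.  As m grows the per-line value l*F_SynL
# tends to (1+F)/2, reached exactly whenever m is a multiple of 4.

#' Decomposition of a line's sample into complete groups and leftovers
#'
#' @slot m plants sampled per line.
#' @slot g number of complete four-plant groups, `floor(m/4)`.
#' @slot e leftover plants that fail to form a group, `m %% 4`.
#' @seealso [decomposeSample()]
#' @exportClass SampleDesign
setClass("SampleDesign", representation(m = "integer", g = "integer", e = "integer"),
         validity = function(object) {
  if (object@m < 1L) return("m must be >= 1")
  if (object@e < 0L || object@e > 3L) return("e must be in 0..3")
  if (object@m != 4L * object@g + object@e) return("m must equal 4g + e")
  TRUE
})

#' @export
setMethod("show", "SampleDesign", function(object) {
  cat("SampleDesign: m = ", object@m, " = 4*", object@g, " + ", object@e, "\n", sep = "")
})

#' Decompose a per-line sample size into groups and leftovers
#'
#' @param m plants sampled per line, integer >= 1.
#' @return A [SampleDesign] with `g = floor(m/4)` and `e = m %% 4`.
#' @examples
#' decomposeSample(15)  # g = 3, e = 3
#' @export
decomposeSample <- function(m) {
  if (length(m) != 1L || !is.numeric(m) || m != floor(m) || m < 1)
    stop("m must be a single integer >= 1")
  m <- as.integer(m)
  new("SampleDesign", m = m, g = m %/% 4L, e = m %% 4L)
}

#' Accessors for a sample design
#' @param x a [SampleDesign].
#' @return integer.
#' @export
nGroups <- function(x) { stopifnot(is(x, "SampleDesign")); x@g }

#' @rdname nGroups
#' @export
nLeftover <- function(x) { stopifnot(is(x, "SampleDesign")); x@e }

#' Inbreeding coefficient of a synthetic variety
#'
#' Holds the exact inbreeding coefficient of a synthetic formed by random
#' mating of m plants from each of l unrelated lines of inbreeding F, plus the
#' per-line value l*F_SynL on which the asymptotics are usually read.
#'
#' @slot m,l integers.
#' @slot F parental inbreeding coefficient, a [Rational].
#' @slot fSynL the variety's inbreeding coefficient, a [Rational].
#' @slot perLineValue l*fSynL, a [Rational] in \[(1+F)/2, (3+F)/4\].
#' @exportClass SyntheticICResult
setClass("SyntheticICResult",
         representation(m = "integer", F = "Rational", l = "integer",
                        fSynL = "Rational", perLineValue = "Rational"),
         validity = function(object) {
  f <- .ri(object@F)
  per <- .ri(object@perLineValue)
  lo <- .rDiv(.rAdd(.rOne, f), .rFromInt(2))
  hi <- .rDiv(.rAdd(.rFromInt(3), f), .rFromInt(4))
  if (.rCmp(per, lo) < 0L || .rCmp(per, hi) > 0L)
    return("per-line value outside [(1+F)/2, (3+F)/4]")
  if (.rCmp(.rMul(.ri(object@fSynL), .rFromInt(object@l)), per) != 0L)
    return("perLineValue must equal l * fSynL")
  TRUE
})

#' @export
setMethod("show", "SyntheticICResult", function(object) {
  cat("Synthetic-variety inbreeding coefficient\n")
  cat("  m = ", object@m, ", F = ", .rToChar(.ri(object@F)),
      ", l = ", object@l, "\n", sep = "")
  cat("  F_SynL        = ", .rToChar(.ri(object@fSynL)),
      " (", format(.rToNum(.ri(object@fSynL)), digits = 6), ")\n", sep = "")
  cat("  l * F_SynL    = ", .rToChar(.ri(object@perLineValue)),
      " (", format(.rToNum(.ri(object@perLineValue)), digits = 6), ")\n", sep = "")
})

#' Accessors for a synthetic-variety inbreeding result
#' @param x a [SyntheticICResult].
#' @return a [Rational].
#' @export
fSynL <- function(x) { stopifnot(is(x, "SyntheticICResult")); x@fSynL }

#' @rdname fSynL
#' @export
perLineValue <- function(x) { stopifnot(is(x, "SyntheticICResult")); x@perLineValue }

# internal: per-line value as an internal rational
.perLine <- function(m, f) {
  d <- decomposeSample(m)
  g <- as.numeric(d@g); e <- as.numeric(d@e)
  selfings <- .rMul(.rFromInt(m), .rDiv(.rAdd(.rFromInt(3), f), .rFromInt(4)))
  within <- .rMul(.rFromInt(12 * g + e * (e - 1)),
                  .rDiv(.rAdd(.rFromInt(5), .rMul(.rFromInt(7), f)), .rFromInt(12)))
  between <- .rMul(.rFromInt(16 * g * (g - 1) + 8 * g * e),
                   .rDiv(.rAdd(.rOne, f), .rFromInt(2)))
  .rDiv(.rAdd(.rAdd(selfings, within), between), .rFromInt(m * m))
}

#' Exact inbreeding coefficient of a synthetic variety
#'
#' Evaluates the finite-sample inbreeding coefficient of a synthetic variety
#' formed by random mating of m plants from each of l unrelated parental lines
#' of inbreeding F, with the sample of each line structured as g complete
#' four-plant groups plus e leftover plants (see [decomposeSample()]).  All
#' arithmetic is exact.
#'
#' @param m plants per line, integer >= 1.
#' @param F parental-line inbreeding coefficient in \[0, 1\].
#' @param l number of unrelated parental lines, integer >= 1.
#' @return A [SyntheticICResult].
#' @examples
#' syntheticIC(1, 0, 1)                    # per-line value 3/4
#' asNumeric(perLineValue(syntheticIC(5, 0.5, 1)))
#' @export
syntheticIC <- function(m, F, l = 1L) {
  if (length(l) != 1L || !is.numeric(l) || l != floor(l) || l < 1)
    stop("l must be a single integer >= 1")
  f <- .checkF(F)
  per <- .perLine(m, f)
  new("SyntheticICResult", m = as.integer(m), F = .R(f), l = as.integer(l),
      fSynL = .R(.rDiv(per, .rFromInt(l))), perLineValue = .R(per))
}

#' Large-sample limit of the per-line inbreeding value
#'
#' As m grows (and exactly whenever m is a multiple of 4) the per-line value
#' l*F_SynL converges to (1+F)/2, the Hardy-Weinberg value for the line's
#' progeny; divide by l for the variety-level coefficient.
#'
#' @param F parental-line inbreeding coefficient in \[0, 1\].
#' @return A [Rational].
#' @examples
#' asNumeric(icAsymptote(0))  # 0.5
#' @export
icAsymptote <- function(F) {
  f <- .checkF(F)
  .R(.rDiv(.rAdd(.rOne, f), .rFromInt(2)))
}

#' Grid of per-line inbreeding values over m and F
#'
#' Tabulates the per-line value l*F_SynL for every combination of sample size
#' and parental inbreeding coefficient, rounded half-away-from-zero.  The
#' defaults reproduce the package's reference grid (m = 1..24 crossed with
#' F in 0, 0.5, 0.75, 0.875, 1).  Divide entries by l for the variety-level
#' coefficient.
#'
#' @param mValues integer vector of sample sizes.
#' @param fValues numeric (or list of [Rational]) parental inbreeding values.
#' @param digits decimal places for rounding (half-away-from-zero).
#' @return A data.frame with columns `m`, `e`, then one column per F value.
#' @examples
#' head(icTable())
#' @export
icTable <- function(mValues = 1:24,
                    fValues = c(0, 0.5, 0.75, 0.875, 1),
                    digits = 2) {
  if (!is.list(fValues)) fValues <- as.list(fValues)
  fr <- lapply(fValues, .checkF)
  out <- data.frame(m = as.integer(mValues),
                    e = as.integer(mValues) %% 4L)
  for (j in seq_along(fr)) {
    col <- vapply(mValues, function(m) {
      r <- .perLine(m, fr[[j]])
      ratRound(.R(r), digits)
    }, numeric(1))
    lbl <- sprintf("F%.4f", .rToNum(fr[[j]]))
    out[[lbl]] <- col
  }
  out
}
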