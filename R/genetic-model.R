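# Genotypic arrays and identity-by-descent coefficients for the progeny of a
# selfed heterozygous line A1A2 whose own inbreeding coefficient is F, i.e.
# P(A1 and A2 identical by descent) = F.  Selfing yields the four ordered
# genotypes A1A1, A1A2, A2A1, A2A2 with probability 1/4 each; merging the two
# heterozygote orders gives the collapsed three-class array (1/4, 1/2, 1/4).

.GENOTYPES4 <- c("A1A1", "A1A2", "A2A1", "A2A2")
.GENOTYPES3 <- c("A1A1", "A1A2", "A2A2")

#' Genotypic array of a selfed line
#'
#' A labelled list of genotypes with exact rational probabilities.  Two
#' canonical arrays exist: the four-class array from selfing a heterozygous
#' line A1A2 (ordered heterozygotes A1A2 and A2A1 kept distinct, probability
#' 1/4 each) and its collapsed three-class form (1/4, 1/2, 1/4).
#'
#' @slot labels character vector of genotype labels.
#' @slot probs list of [Rational] probabilities, summing exactly to one.
#' @slot arity 3L or 4L, the number of genotype classes.
#' @seealso [selfedLineArray()], [collapseToGA3()]
#' @exportClass GenotypicArray
setClass("GenotypicArray",
         representation(labels = "character", probs = "list", arity = "integer"),
         validity = function(object) {
  if (!object@arity %in% c(3L, 4L)) return("arity must be 3 or 4")
  if (length(object@labels) != object@arity) return("labels do not match arity")
  if (length(object@probs) != object@arity) return("probs do not match arity")
  if (!all(vapply(object@probs, is, logical(1), class2 = "Rational")))
    return("probs must all be Rational")
  tot <- .rZero
  for (p in object@probs) {
    pi <- .ri(p)
    if (pi$s < 0L) return("probabilities must be nonnegative")
    tot <- .rAdd(tot, pi)
  }
  if (.rCmp(tot, .rOne) != 0L) return("probabilities must sum exactly to 1")
  TRUE
})

#' @export
setMethod("show", "GenotypicArray", function(object) {
  cat("GenotypicArray (", object@arity, " classes)\n", sep = "")
  for (i in seq_len(object@arity))
    cat("  ", object@labels[i], ": ", .rToChar(.ri(object@probs[[i]])), "\n", sep = "")
})

#' Number of genotype classes of an array
#' @param x a [GenotypicArray].
#' @return integer, 3 or 4.
#' @export
arity <- function(x) {
  stopifnot(is(x, "GenotypicArray"))
  x@arity
}

#' Genotype labels of an array
#' @param x a [GenotypicArray].
#' @return character vector.
#' @export
genotypeLabels <- function(x) {
  stopifnot(is(x, "GenotypicArray"))
  x@labels
}

#' Genotype probabilities of an array
#' @param x a [GenotypicArray].
#' @param numeric if `TRUE` return doubles instead of [Rational] objects.
#' @return named list of [Rational], or a named numeric vector.
#' @export
genotypeProbs <- function(x, numeric = FALSE) {
  stopifnot(is(x, "GenotypicArray"))
  if (numeric) {
    out <- vapply(x@probs, function(p) .rToNum(.ri(p)), numeric(1))
    names(out) <- x@labels
    return(out)
  }
  stats::setNames(x@probs, x@labels)
}

# internal: probabilities as internal rational lists
.gaProbs <- function(ga) lapply(ga@probs, .ri)

#' The four-class genotypic array produced by selfing a heterozygous line
#'
#' Selfing A1A2 produces the ordered genotypes A1A1, A1A2, A2A1 and A2A2,
#' each with probability exactly 1/4.  The two heterozygote orders are kept
#' distinct: they are distinct sampling outcomes even though they are
#' genetically identical, and collapsing them is an explicit operation
#' ([collapseToGA3()]), never implicit.
#'
#' @return A [GenotypicArray] with arity 4.
#' @examples
#' selfedLineArray()
#' @export
selfedLineArray <- function() {
  q <- rational(1, 4)
  new("GenotypicArray", labels = .GENOTYPES4,
      probs = list(q, q, q, q), arity = 4L)
}

#' Collapse the four-class array to three genotype classes
#'
#' Merges the two ordered heterozygotes A1A2 and A2A1 into a single class,
#' giving probabilities (1/4, 1/2, 1/4) over A1A1, A1A2, A2A2.  Homozygote
#' probabilities are untouched.
#'
#' @param ga a [GenotypicArray] with arity 4.
#' @return A [GenotypicArray] with arity 3.
#' @examples
#' collapseToGA3(selfedLineArray())
#' @export
collapseToGA3 <- function(ga) {
  stopifnot(is(ga, "GenotypicArray"))
  if (ga@arity != 4L) stop("collapseToGA3() needs a four-class array")
  new("GenotypicArray", labels = .GENOTYPES3,
      probs = list(ga@probs[[1L]], ga@probs[[2L]] + ga@probs[[3L]], ga@probs[[4L]]),
      arity = 3L)
}

# F validation: accepts Rational or numeric, returns internal rational in [0,1]
.checkF <- function(F) {
  r <- .ri(asRational(F))
  if (.rCmp(r, .rZero) < 0L || .rCmp(r, .rOne) > 0L)
    stop("F must lie in [0, 1]")
  r
}

#' Linear form a + b*F
#'
#' The inbreeding coefficient of every mating among the selfed-line genotypes
#' is linear in the parental inbreeding coefficient F, so it is stored as an
#' exact pair (a, b) meaning a + b*F.
#'
#' @slot a intercept, a [Rational].
#' @slot b slope on F, a [Rational].
#' @exportClass ICForm
setClass("ICForm", representation(a = "Rational", b = "Rational"))

#' @export
setMethod("show", "ICForm", function(object) {
  cat(.rToChar(.ri(object@a)), " + ", .rToChar(.ri(object@b)), "*F\n", sep = "")
})

#' Evaluate a linear inbreeding-coefficient form at a given F
#' @param form an [ICForm].
#' @param F parental inbreeding coefficient in \[0, 1\].
#' @return A [Rational].
#' @export
icFormEval <- function(form, F) {
  stopifnot(is(form, "ICForm"))
  f <- .checkF(F)
  .R(.rAdd(.ri(form@a), .rMul(.ri(form@b), f)))
}

.isHom <- function(g) g %in% c("A1A1", "A2A2")

# the (a, b) linear form for one ordered mating; p1 == p2 means selfing
.progenyForm <- function(p1, p2) {
  if (.isHom(p1) && .isHom(p2)) {
    if (p1 == p2) return(list(a = .rOne, b = .rZero))      # selfing a homozygote
    return(list(a = .rZero, b = .rOne))                    # A1A1 x A2A2 -> F
  }
  half <- .rMake(1L, 1, 2)
  list(a = half, b = half)                                 # everything else: (1+F)/2
}

#' Inbreeding coefficient of the progeny of one mating
#'
#' For two plants drawn from the selfed progeny of a line A1A2 with
#' P(A1 identical-by-descent A2) = F, the progeny inbreeding coefficient is:
#' 1 for selfing a homozygote; F for the cross of opposite homozygotes
#' (A1A1 x A2A2); and (1+F)/2 for every other selfing or cross, including
#' reciprocals.
#'
#' @param p1,p2 genotype labels among `"A1A1"`, `"A1A2"`, `"A2A1"`, `"A2A2"`;
#'   `p1 == p2` denotes selfing.
#' @param F parental-line inbreeding coefficient in \[0, 1\] (numeric or
#'   [Rational]).
#' @return A [Rational].
#' @examples
#' progenyIC("A1A1", "A1A1", 0)    # 1
#' progenyIC("A1A1", "A2A2", 0.5)  # F = 1/2
#' progenyIC("A1A2", "A2A1", 0)    # 1/2
#' @export
progenyIC <- function(p1, p2, F) {
  p1 <- match.arg(p1, .GENOTYPES4)
  p2 <- match.arg(p2, .GENOTYPES4)
  f <- .checkF(F)
  form <- .progenyForm(p1, p2)
  .R(.rAdd(form$a, .rMul(form$b, f)))
}

#' Linear form of the progeny inbreeding coefficient for one mating
#'
#' @inheritParams progenyIC
#' @return An [ICForm] with intercept and slope on F.
#' @export
progenyICForm <- function(p1, p2) {
  p1 <- match.arg(p1, .GENOTYPES4)
  p2 <- match.arg(p2, .GENOTYPES4)
  form <- .progenyForm(p1, p2)
  new("ICForm", a = .R(form$a), b = .R(form$b))
}

#' Table of progeny inbreeding coefficients over all ordered matings
#'
#' The 4 x 4 table of [ICForm] linear forms indexed by the ordered pair of
#' parental genotypes of the selfed-line array, including the four selfings
#' on the diagonal.  Every row mean, column mean and the global mean equals
#' (1+F)/2.
#'
#' @slot genotypes the four ordered genotype labels.
#' @slot forms list of 16 [ICForm] objects, row-major.
#' @exportClass MatingICTable
setClass("MatingICTable", representation(genotypes = "character", forms = "list"),
         validity = function(object) {
  if (length(object@genotypes) != 4L) return("four genotypes required")
  if (length(object@forms) != 16L) return("sixteen forms required")
  # symmetry in the two parent indices
  for (i in 1:4) for (j in 1:4) {
    fij <- object@forms[[(i - 1L) * 4L + j]]
    fji <- object@forms[[(j - 1L) * 4L + i]]
    if (.rCmp(.ri(fij@a), .ri(fji@a)) != 0L || .rCmp(.ri(fij@b), .ri(fji@b)) != 0L)
      return("mating table must be symmetric in its parents")
  }
  TRUE
})

#' Build the mating inbreeding-coefficient table
#' @return A [MatingICTable].
#' @examples
#' tab <- matingICTable()
#' icFormEval(grandMeanIC(tab), 0)   # 1/2
#' @export
matingICTable <- function() {
  forms <- vector("list", 16L)
  for (i in 1:4) for (j in 1:4)
    forms[[(i - 1L) * 4L + j]] <- progenyICForm(.GENOTYPES4[i], .GENOTYPES4[j])
  new("MatingICTable", genotypes = .GENOTYPES4, forms = forms)
}

.formsMean <- function(forms) {
  n <- .rFromInt(length(forms))
  a <- .rZero; b <- .rZero
  for (f in forms) {
    a <- .rAdd(a, .ri(f@a))
    b <- .rAdd(b, .ri(f@b))
  }
  new("ICForm", a = .R(.rDiv(a, n)), b = .R(.rDiv(b, n)))
}

#' Mean inbreeding coefficient of one parent's row of the mating table
#' @param x a [MatingICTable].
#' @param genotype one of the four genotype labels.
#' @return An [ICForm]; always (1+F)/2.
#' @export
rowMeanIC <- function(x, genotype) {
  stopifnot(is(x, "MatingICTable"))
  i <- match(match.arg(genotype, x@genotypes), x@genotypes)
  .formsMean(x@forms[(i - 1L) * 4L + 1:4])
}

#' Global mean inbreeding coefficient of the mating table
#' @param x a [MatingICTable].
#' @return An [ICForm]; always (1+F)/2.
#' @export
grandMeanIC <- function(x) {
  stopifnot(is(x, "MatingICTable"))
  .formsMean(x@forms)
}

#' @export
setMethod("show", "MatingICTable", function(object) {
  cat("MatingICTable (progeny inbreeding coefficients, a + b*F)\n")
  txt <- vapply(object@forms, function(f)
    paste0(.rToChar(.ri(f@a)), "+", .rToChar(.ri(f@b)), "F"), character(1))
  m <- matrix(txt, 4, 4, byrow = TRUE,
              dimnames = list(object@genotypes, object@genotypes))
  print(m, quote = FALSE)
})

#' Group-average inbreeding coefficients
#'
#' Averages of the progeny inbreeding coefficient over the matings within one
#' complete four-plant group holding the selfed-line genotypes:
#' `meanSelfingIC()` averages the 4 selfings, giving (3+F)/4;
#' `meanWithinGroupCrossIC()` averages the 12 ordered within-group crosses,
#' giving (5+7F)/12 (it is pulled below (1+F)/2 by the two opposite-homozygote
#' crosses whose progeny coefficient is F);
#' `meanBetweenGroupIC()` averages the 16 ordered crosses between two complete
#' groups, giving (1+F)/2.
#'
#' @param F parental-line inbreeding coefficient in \[0, 1\].
#' @return A [Rational].
#' @examples
#' asNumeric(meanSelfingIC(0))          # 0.75
#' asNumeric(meanWithinGroupCrossIC(0)) # 5/12
#' asNumeric(meanBetweenGroupIC(0))     # 0.5
#' @export
meanSelfingIC <- function(F) {
  f <- .checkF(F)
  .R(.rDiv(.rAdd(.rFromInt(3), f), .rFromInt(4)))
}

#' @rdname meanSelfingIC
#' @export
meanWithinGroupCrossIC <- function(F) {
  f <- .checkF(F)
  .R(.rDiv(.rAdd(.rFromInt(5), .rMul(.rFromInt(7), f)), .rFromInt(12)))
}

#' @rdname meanSelfingIC
#' @export
meanBetweenGroupIC <- function(F) {
  f <- .checkF(F)
  .R(.rDiv(.rAdd(.rOne, f), .rFromInt(2)))
}
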