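# Exact rational numbers on top of the bignat layer.
#
# Internally a rational is a plain list(s = sign in {-1L,0L,1L}, n, d) with
# bignat magnitude n and positive bignat denominator d, always reduced.  The
# exported S4 class `Rational` wraps the same three fields; hot loops in the
# analytic modules work on the internal lists and convert at the boundary.

.rMake <- function(s, n, d) {
  if (.bnIsZero(d)) stop("zero denominator")
  if (.bnIsZero(n)) return(list(s = 0L, n = 0, d = 1))
  g <- .bnGcd(n, d)
  if (!(length(g) == 1L && g[1L] == 1)) {
    n <- .bnDivMod(n, g)$q
    d <- .bnDivMod(d, g)$q
  }
  list(s = as.integer(s), n = n, d = d)
}

.rFromInt <- function(v) {
  s <- if (v > 0) 1L else if (v < 0) -1L else 0L
  list(s = s, n = .bnFromNum(abs(v)), d = 1)
}

.rZero <- list(s = 0L, n = 0, d = 1)
.rOne  <- list(s = 1L, n = 1, d = 1)

# signed addition of (s1, n1) + (s2, n2) over a common denominator
.snAdd <- function(s1, n1, s2, n2) {
  if (s1 == 0L) return(list(s = s2, n = n2))
  if (s2 == 0L) return(list(s = s1, n = n1))
  if (s1 == s2) return(list(s = s1, n = .bnAdd(n1, n2)))
  cmp <- .bnCmp(n1, n2)
  if (cmp == 0L) return(list(s = 0L, n = 0))
  if (cmp > 0L) list(s = s1, n = .bnSub(n1, n2)) else list(s = s2, n = .bnSub(n2, n1))
}

.rAdd <- function(x, y) {
  if (.bnCmp(x$d, y$d) == 0L) {
    sn <- .snAdd(x$s, x$n, y$s, y$n)
    return(.rMake(sn$s, sn$n, x$d))
  }
  sn <- .snAdd(x$s, .bnMul(x$n, y$d), y$s, .bnMul(y$n, x$d))
  .rMake(sn$s, sn$n, .bnMul(x$d, y$d))
}

.rNeg <- function(x) list(s = -x$s, n = x$n, d = x$d)

.rSub <- function(x, y) .rAdd(x, .rNeg(y))

.rMul <- function(x, y) {
  if (x$s == 0L || y$s == 0L) return(.rZero)
  .rMake(x$s * y$s, .bnMul(x$n, y$n), .bnMul(x$d, y$d))
}

.rDiv <- function(x, y) {
  if (y$s == 0L) stop("rational division by zero")
  if (x$s == 0L) return(.rZero)
  .rMake(x$s * y$s, .bnMul(x$n, y$d), .bnMul(x$d, y$n))
}

.rPowInt <- function(x, k) {
  k <- as.numeric(k)
  if (k != floor(k)) stop("rational exponent must be an integer")
  if (k == 0) return(.rOne)
  if (k < 0) return(.rPowInt(.rDiv(.rOne, x), -k))
  s <- if (x$s == 0L) 0L else if (x$s < 0L && k %% 2 == 1) -1L else if (x$s < 0L) 1L else 1L
  list(s = s, n = .bnPow(x$n, k), d = .bnPow(x$d, k))
}

.rCmp <- function(x, y) {
  if (x$s != y$s) return(if (x$s < y$s) -1L else 1L)
  if (x$s == 0L) return(0L)
  cmp <- .bnCmp(.bnMul(x$n, y$d), .bnMul(y$n, x$d))
  if (x$s > 0L) cmp else -cmp
}

.rToNum <- function(x) x$s * (.bnToNum(x$n) / .bnToNum(x$d))

.rToChar <- function(x) {
  sgn <- if (x$s < 0L) "-" else ""
  if (length(x$d) == 1L && x$d[1L] == 1) paste0(sgn, .bnToString(x$n))
  else paste0(sgn, .bnToString(x$n), "/", .bnToString(x$d))
}

#' Exact rational numbers
#'
#' `Rational` holds one exact rational number with an arbitrary-precision
#' integer numerator and denominator, always stored in lowest terms with the
#' sign carried separately.  Every analytic quantity in this package (genotype
#' probabilities, inbreeding coefficients, inclusion probabilities) is a ratio
#' of integers, so the whole analytic layer computes on this class and only
#' converts to floating point for display.
#'
#' Standard arithmetic (`+`, `-`, `*`, `/`, `^` with integer exponent) and
#' comparison operators are defined between two `Rational` objects and between
#' a `Rational` and a numeric scalar (the numeric is converted exactly; every
#' double is a dyadic rational).
#'
#' @slot s sign, one of -1L, 0L, 1L.
#' @slot n numerator magnitude (internal base-1e7 digit vector).
#' @slot d denominator magnitude (internal base-1e7 digit vector), positive.
#'
#' @examples
#' rational(1, 4) + rational(1, 2)
#' asNumeric(rational(3, 16))
#' @name Rational-class
#' @aliases Rational
#' @exportClass Rational
setClass("Rational", representation(s = "integer", n = "numeric", d = "numeric"),
         validity = function(object) {
  if (length(object@s) != 1L || !object@s %in% c(-1L, 0L, 1L))
    return("sign must be -1, 0 or 1")
  if (object@s == 0L && !.bnIsZero(object@n))
    return("zero sign with nonzero numerator")
  if (.bnIsZero(object@d)) return("zero denominator")
  TRUE
})

# boundary converters between the internal list form and the S4 class
.ri <- function(x) list(s = x@s, n = x@n, d = x@d)
.R <- function(r) new("Rational", s = r$s, n = r$n, d = r$d)

#' Construct an exact rational number
#'
#' @param num integer-valued numeric numerator (|num| < 2^53).
#' @param den integer-valued numeric denominator, nonzero.
#' @return A [Rational] object in lowest terms.
#' @examples
#' rational(90, 1024)
#' @export
rational <- function(num, den = 1) {
  stopifnot(length(num) == 1L, length(den) == 1L, is.numeric(num), is.numeric(den))
  if (num != floor(num) || den != floor(den)) stop("num and den must be integers")
  if (den == 0) stop("zero denominator")
  s <- sign(num) * sign(den)
  .R(.rMake(as.integer(s), .bnFromNum(abs(num)), .bnFromNum(abs(den))))
}

# exact conversion of a double: every finite double is m * 2^k
.rFromNumericExact <- function(x) {
  if (!is.finite(x)) stop("cannot convert a non-finite value to Rational")
  if (x == floor(x) && abs(x) <= 2^53) return(.rFromInt(x))
  k <- 0L
  while (x != floor(x)) {
    x <- x * 2
    k <- k + 1L
  }
  .rMake(as.integer(sign(x)), .bnFromNum(abs(x)), .bnPow(.bnFromNum(2), k))
}

#' Coerce to Rational
#'
#' Numeric scalars convert exactly via their binary representation (a double
#' is always a dyadic rational, so e.g. `0.875` becomes 7/8 with no rounding).
#'
#' @param x a [Rational] or a finite numeric scalar.
#' @return A [Rational].
#' @export
asRational <- function(x) {
  if (is(x, "Rational")) return(x)
  stopifnot(is.numeric(x), length(x) == 1L)
  .R(.rFromNumericExact(x))
}

#' Convert a package object to its floating-point value
#'
#' @param x object to convert.
#' @param ... unused.
#' @return numeric value(s); exact rationals are rendered at double precision.
#' @export
setGeneric("asNumeric", function(x, ...) standardGeneric("asNumeric"))

#' @rdname asNumeric
#' @export
setMethod("asNumeric", "Rational", function(x, ...) .rToNum(.ri(x)))

#' @export
setMethod("show", "Rational", function(object) {
  cat("Rational: ", .rToChar(.ri(object)), "\n", sep = "")
})

#' @export
setMethod("as.character", "Rational", function(x, ...) .rToChar(.ri(x)))

.ratArith <- function(op, x, y) {
  switch(op,
    "+" = .R(.rAdd(x, y)),
    "-" = .R(.rSub(x, y)),
    "*" = .R(.rMul(x, y)),
    "/" = .R(.rDiv(x, y)),
    "^" = stop("use Rational ^ integer"),
    stop("unsupported operation '", op, "' for Rational")
  )
}

#' @export
setMethod("Arith", signature("Rational", "Rational"), function(e1, e2) {
  .ratArith(.Generic, .ri(e1), .ri(e2))
})

#' @export
setMethod("Arith", signature("Rational", "numeric"), function(e1, e2) {
  if (.Generic == "^") return(.R(.rPowInt(.ri(e1), e2)))
  .ratArith(.Generic, .ri(e1), .rFromNumericExact(e2))
})

#' @export
setMethod("Arith", signature("numeric", "Rational"), function(e1, e2) {
  .ratArith(.Generic, .rFromNumericExact(e1), .ri(e2))
})

.ratCompare <- function(op, x, y) {
  cmp <- .rCmp(x, y)
  switch(op,
    "==" = cmp == 0L, "!=" = cmp != 0L,
    "<" = cmp < 0L, "<=" = cmp <= 0L,
    ">" = cmp > 0L, ">=" = cmp >= 0L)
}

#' @export
setMethod("Compare", signature("Rational", "Rational"), function(e1, e2) {
  .ratCompare(.Generic, .ri(e1), .ri(e2))
})

#' @export
setMethod("Compare", signature("Rational", "numeric"), function(e1, e2) {
  .ratCompare(.Generic, .ri(e1), .rFromNumericExact(e2))
})

#' @export
setMethod("Compare", signature("numeric", "Rational"), function(e1, e2) {
  .ratCompare(.Generic, .rFromNumericExact(e1), .ri(e2))
})

# exact decimal rendering helpers -------------------------------------------

.rScaleDigits <- function(r, digits) {
  # returns list(q = integer part of |r|*10^digits as double, rem, den)
  n10 <- .bnMul(r$n, .bnPow(.bnFromNum(10), digits))
  qr <- .bnDivMod(n10, r$d)
  list(q = .bnToNum(qr$q), rem = qr$r, den = r$d)
}

#' Round an exact rational half-away-from-zero
#'
#' Decimal tables in this package are rendered by rounding half-away-from-zero
#' (so 0.9375 at 2 decimals is 0.94, and 0.5833... is 0.58), computed exactly
#' on the rational rather than on a double.
#'
#' @param x a [Rational] (or numeric, converted exactly).
#' @param digits number of decimal places.
#' @return numeric scalar.
#' @examples
#' ratRound(rational(15, 16), 2)   # 0.94
#' @export
ratRound <- function(x, digits = 4) {
  r <- .ri(asRational(x))
  if (r$s == 0L) return(0)
  sc <- .rScaleDigits(r, digits)
  q <- sc$q
  if (.bnCmp(.bnMulSmall(sc$rem, 2), sc$den) >= 0L) q <- q + 1
  r$s * q / 10^digits
}

#' Truncate an exact rational to a number of decimals
#'
#' @inheritParams ratRound
#' @return numeric scalar, truncated toward zero.
#' @examples
#' ratTruncate(rational(2, 1024), 4)  # 0.0019
#' @export
ratTruncate <- function(x, digits = 4) {
  r <- .ri(asRational(x))
  if (r$s == 0L) return(0)
  sc <- .rScaleDigits(r, digits)
  r$s * sc$q / 10^digits
}

# exact sum of a list of internal rationals sharing one denominator fast path
.rSum <- function(lst) {
  acc <- .rZero
  for (x in lst) acc <- .rAdd(acc, x)
  acc
}
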