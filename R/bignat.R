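# Internal arbitrary-precision natural-number arithmetic.
#
# A "bignat" is a numeric vector of base-1e7 digits, little-endian, with no
# trailing zero digits (the number zero is the single digit 0).  All digits
# are integer-valued doubles in [0, 1e7), so every intermediate product
# digit*digit + carry stays far below 2^53 and is exact.

.BN_BASE <- 1e7

.bnTrim <- function(x) {
  n <- length(x)
  while (n > 1L && x[n] == 0) n <- n - 1L
  if (n == length(x)) x else x[seq_len(n)]
}

# exact divmod of an integer-valued double v (< 2^53) by an integer s
.dqr <- function(v, s) {
  q <- floor(v / s)
  r <- v - q * s
  if (r < 0) { q <- q - 1; r <- r + s } else if (r >= s) { q <- q + 1; r <- r - s }
  c(q, r)
}

.bnFromNum <- function(v) {
  if (v < 0 || v != floor(v) || v > 2^53)
    stop("bignat seed must be a nonnegative integer-valued double below 2^53")
  if (v == 0) return(0)
  d <- numeric(0)
  while (v > 0) {
    qr <- .dqr(v, .BN_BASE)
    d <- c(d, qr[2L])
    v <- qr[1L]
  }
  d
}

.bnIsZero <- function(a) length(a) == 1L && a[1L] == 0

# -1, 0, 1 as a <, ==, > b
.bnCmp <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la != lb) return(if (la < lb) -1L else 1L)
  for (i in rev(seq_len(la))) {
    if (a[i] != b[i]) return(if (a[i] < b[i]) -1L else 1L)
  }
  0L
}

.bnAdd <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    t <- s[i] + carry
    if (t >= .BN_BASE) { s[i] <- t - .BN_BASE; carry <- 1 } else { s[i] <- t; carry <- 0 }
  }
  if (carry) s <- c(s, 1)
  s
}

# requires a >= b
.bnSub <- function(a, b) {
  b <- c(b, numeric(length(a) - length(b)))
  d <- a - b
  borrow <- 0
  for (i in seq_along(d)) {
    t <- d[i] - borrow
    if (t < 0) { d[i] <- t + .BN_BASE; borrow <- 1 } else { d[i] <- t; borrow <- 0 }
  }
  if (borrow) stop("bignat underflow")
  .bnTrim(d)
}

# s: integer-valued double with s < 2^26 guaranteed safe; digits*s <= 1e7*s
.bnMulSmall <- function(a, s) {
  if (s == 0 || .bnIsZero(a)) return(0)
  p <- a * s
  carry <- 0
  out <- numeric(length(p))
  for (i in seq_along(p)) {
    t <- p[i] + carry
    qr <- .dqr(t, .BN_BASE)
    out[i] <- qr[2L]
    carry <- qr[1L]
  }
  while (carry > 0) {
    qr <- .dqr(carry, .BN_BASE)
    out <- c(out, qr[2L])
    carry <- qr[1L]
  }
  .bnTrim(out)
}

.bnMul <- function(a, b) {
  if (.bnIsZero(a) || .bnIsZero(b)) return(0)
  acc <- 0
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    part <- .bnMulSmall(b, a[i])
    if (i > 1L) part <- c(numeric(i - 1L), part)
    acc <- .bnAdd(acc, part)
  }
  acc
}

# divide by an integer-valued double s (0 < s <= 9e8); returns list(q, r)
.bnDivSmall <- function(a, s) {
  q <- numeric(length(a))
  r <- 0
  for (i in rev(seq_along(a))) {
    cur <- r * .BN_BASE + a[i]
    qr <- .dqr(cur, s)
    q[i] <- qr[1L]
    r <- qr[2L]
  }
  list(q = .bnTrim(q), r = r)
}

# binary long division: q, r with a = q*b + r, 0 <= r < b
.bnDivMod <- function(a, b) {
  if (.bnIsZero(b)) stop("bignat division by zero")
  cmp <- .bnCmp(a, b)
  if (cmp < 0) return(list(q = 0, r = a))
  if (length(b) == 1L) {
    out <- .bnDivSmall(a, b[1L])
    return(list(q = out$q, r = out$r))
  }
  # collect the bits of a, least significant first
  bits <- numeric(0)
  t <- a
  while (!.bnIsZero(t)) {
    hv <- .bnDivSmall(t, 2)
    bits <- c(bits, hv$r)
    t <- hv$q
  }
  q <- 0
  r <- 0
  for (i in rev(seq_along(bits))) {
    r <- .bnMulSmall(r, 2)
    if (bits[i]) r <- .bnAdd(r, 1)
    q <- .bnMulSmall(q, 2)
    if (.bnCmp(r, b) >= 0) {
      r <- .bnSub(r, b)
      q <- .bnAdd(q, 1)
    }
  }
  list(q = q, r = r)
}

.bnGcd <- function(a, b) {
  while (!.bnIsZero(b)) {
    r <- .bnDivMod(a, b)$r
    a <- b
    b <- r
  }
  a
}

.bnPow <- function(a, n) {
  if (n < 0 || n != floor(n)) stop("bignat exponent must be a nonnegative integer")
  out <- 1
  base <- a
  while (n > 0) {
    if (n %% 2 == 1) out <- .bnMul(out, base)
    n <- n %/% 2
    if (n > 0) base <- .bnMul(base, base)
  }
  out
}

# factorial with memoisation; n is small (tens) in every caller
.bnFactCache <- new.env(parent = emptyenv())
.bnFactorial <- function(n) {
  if (n < 0 || n != floor(n)) stop("factorial of a negative or fractional number")
  key <- as.character(n)
  hit <- .bnFactCache[[key]]
  if (!is.null(hit)) return(hit)
  out <- 1
  if (n >= 2) for (i in 2:n) out <- .bnMulSmall(out, i)
  .bnFactCache[[key]] <- out
  out
}

# lossy conversion for display; exact when the value is below 2^53
.bnToNum <- function(a) {
  v <- 0
  for (i in rev(seq_along(a))) v <- v * .BN_BASE + a[i]
  v
}

.bnToString <- function(a) {
  n <- length(a)
  head <- sprintf("%.0f", a[n])
  if (n == 1L) return(head)
  paste0(head, paste(sprintf("%07.0f", rev(a[-n])), collapse = ""))
}
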