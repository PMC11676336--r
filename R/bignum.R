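# Signed arbitrary-precision integers on base-1e7 digit vectors.
#
# Necklace counts grow like sigma^n / n; for the parameter ranges the bound
# functions accept (e.g. sigma = 256, n = 16) the values exceed 2^53, so the
# bounds cannot be computed exactly in doubles.  Digits are stored
# little-endian as doubles < 1e7; every intermediate product stays below
# 1e14 < 2^53, so all digit arithmetic is exact.

.BN_BASE <- 1e7
.BN_DIGITS <- 7L

#' Construct a big integer
#'
#' @param x a single numeric holding an integer with absolute value below
#'   2^53, or an object that is already a `bigint`.
#' @return an object of class `bigint`.
#' @examples
#' as_bigint(12)
#' as_bigint(-3)
#' @export
as_bigint <- function(x) {
  if (inherits(x, "bigint")) return(x)
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x), x == trunc(x))
  if (abs(x) > 2^53) stop("numeric too large to convert exactly; build it with bigint arithmetic")
  s <- if (x > 0) 1L else if (x < 0) -1L else 0L
  x <- abs(x)
  d <- numeric(0)
  if (x == 0) d <- 0
  while (x > 0) {
    d <- c(d, x %% .BN_BASE)
    x <- x %/% .BN_BASE
  }
  structure(list(s = s, d = d), class = "bigint")
}

.bn_norm <- function(s, d) {
  n <- length(d)
  while (n > 1L && d[n] == 0) n <- n - 1L
  d <- d[seq_len(n)]
  if (n == 1L && d[1L] == 0) s <- 0L
  structure(list(s = s, d = d), class = "bigint")
}

# compare |a| vs |b|: -1, 0, 1
.bn_cmp_abs <- function(a, b) {
  la <- length(a$d); lb <- length(b$d)
  if (la != lb) return(if (la < lb) -1L else 1L)
  for (i in rev(seq_len(la))) {
    if (a$d[i] != b$d[i]) return(if (a$d[i] < b$d[i]) -1L else 1L)
  }
  0L
}

.bn_add_abs <- function(a, b) {
  la <- length(a); lb <- length(b)
  n <- max(la, lb)
  x <- c(a, numeric(n - la)); y <- c(b, numeric(n - lb))
  r <- numeric(n + 1L)
  carry <- 0
  for (i in seq_len(n)) {
    v <- x[i] + y[i] + carry
    r[i] <- v %% .BN_BASE
    carry <- v %/% .BN_BASE
  }
  r[n + 1L] <- carry
  r
}

# requires |a| >= |b|
.bn_sub_abs <- function(a, b) {
  la <- length(a); lb <- length(b)
  x <- a; y <- c(b, numeric(la - lb))
  r <- numeric(la)
  borrow <- 0
  for (i in seq_len(la)) {
    v <- x[i] - y[i] - borrow
    if (v < 0) { v <- v + .BN_BASE; borrow <- 1 } else borrow <- 0
    r[i] <- v
  }
  r
}

#' @export
bn_add <- function(a, b) {
  a <- as_bigint(a); b <- as_bigint(b)
  if (a$s == 0L) return(b)
  if (b$s == 0L) return(a)
  if (a$s == b$s) return(.bn_norm(a$s, .bn_add_abs(a$d, b$d)))
  cmp <- .bn_cmp_abs(a, b)
  if (cmp == 0L) return(as_bigint(0))
  if (cmp > 0L) .bn_norm(a$s, .bn_sub_abs(a$d, b$d)) else .bn_norm(b$s, .bn_sub_abs(b$d, a$d))
}

#' @export
bn_sub <- function(a, b) {
  b <- as_bigint(b)
  bn_add(a, .bn_norm(-b$s, b$d))
}

#' Multiply a big integer by a small integer
#'
#' `m` must satisfy |m| < 1e7 so that digit products remain exact.
#' @export
bn_mul_small <- function(a, m) {
  a <- as_bigint(a)
  stopifnot(is.numeric(m), length(m) == 1L, m == trunc(m), abs(m) < .BN_BASE)
  if (m == 0 || a$s == 0L) return(as_bigint(0))
  s <- a$s * (if (m > 0) 1L else -1L)
  m <- abs(m)
  n <- length(a$d)
  r <- numeric(n + 2L)
  carry <- 0
  for (i in seq_len(n)) {
    v <- a$d[i] * m + carry
    r[i] <- v %% .BN_BASE
    carry <- v %/% .BN_BASE
  }
  i <- n + 1L
  while (carry > 0) {
    r[i] <- carry %% .BN_BASE
    carry <- carry %/% .BN_BASE
    i <- i + 1L
  }
  .bn_norm(s, r)
}

#' Full big x big product
#' @export
bn_mul <- function(a, b) {
  a <- as_bigint(a); b <- as_bigint(b)
  if (a$s == 0L || b$s == 0L) return(as_bigint(0))
  la <- length(a$d); lb <- length(b$d)
  r <- numeric(la + lb + 1L)
  for (i in seq_len(la)) {
    carry <- 0
    ai <- a$d[i]
    if (ai == 0) next
    for (j in seq_len(lb)) {
      # ai * bj <= (1e7-1)^2 < 1e14; adding r (<1e7) and carry (<1e7) stays exact
      v <- r[i + j - 1L] + ai * b$d[j] + carry
      r[i + j - 1L] <- v %% .BN_BASE
      carry <- v %/% .BN_BASE
    }
    jj <- i + lb
    while (carry > 0) {
      v <- r[jj] + carry
      r[jj] <- v %% .BN_BASE
      carry <- v %/% .BN_BASE
      jj <- jj + 1L
    }
  }
  .bn_norm(a$s * b$s, r)
}

#' Integer power with small base
#' @export
bn_pow <- function(base, exp) {
  stopifnot(exp >= 0, exp == trunc(exp))
  r <- as_bigint(1)
  b <- as_bigint(base)
  for (i in seq_len(exp)) r <- if (length(b$d) == 1L) bn_mul_small(r, b$s * b$d[1L]) else bn_mul(r, b)
  r
}

#' Divide by a small positive integer, returning quotient and remainder
#' @export
bn_divmod_small <- function(a, m) {
  a <- as_bigint(a)
  stopifnot(m >= 1, m == trunc(m), m < .BN_BASE)
  n <- length(a$d)
  q <- numeric(n)
  r <- 0
  for (i in rev(seq_len(n))) {
    v <- r * .BN_BASE + a$d[i]
    q[i] <- v %/% m
    r <- v %% m
  }
  list(q = .bn_norm(a$s, q), r = a$s * r)
}

#' @export
bn_eq <- function(a, b) {
  a <- as_bigint(a); b <- as_bigint(b)
  a$s == b$s && .bn_cmp_abs(a, b) == 0L
}

#' Compare two big integers: -1, 0 or 1
#' @export
bn_cmp <- function(a, b) {
  a <- as_bigint(a); b <- as_bigint(b)
  if (a$s != b$s) return(if (a$s < b$s) -1L else 1L)
  if (a$s == 0L) return(0L)
  a$s * .bn_cmp_abs(a, b)
}

.bn_to_double <- function(x) {
  v <- 0
  for (i in rev(seq_along(x$d))) v <- v * .BN_BASE + x$d[i]
  x$s * v
}

#' @export
as.double.bigint <- function(x, ...) .bn_to_double(x)

#' @export
as.character.bigint <- function(x, ...) {
  n <- length(x$d)
  top <- format(x$d[n], scientific = FALSE)
  rest <- if (n > 1L) paste(sprintf("%07.0f", rev(x$d[-n])), collapse = "") else ""
  paste0(if (x$s < 0L) "-" else "", top, rest)
}

#' @export
format.bigint <- function(x, ...) as.character(x)

#' @export
print.bigint <- function(x, ...) {
  cat("<bigint> ", as.character(x), "\n", sep = "")
  invisible(x)
}

# exact-rational ratio of two bigints as a double (relative error ~1e-15):
# both operands convert via Horner with leading-digit dominance, and the
# magnitudes stay far below double overflow for every supported parameter set.
bn_ratio <- function(num, den) {
  .bn_to_double(as_bigint(num)) / .bn_to_double(as_bigint(den))
}
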