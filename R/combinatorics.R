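# Number theory and necklace machinery.
#
# A necklace of length n over an alphabet of size sigma is an equivalence
# class of strings under rotation; it corresponds to a pure cycle of the
# order-n De Bruijn graph.  The counting functions below follow the classical
# Moreau/MacMahon formulas: N_sigma(n) = (1/n) sum_{p|n} phi(n/p) sigma^p and
# M_sigma(n) = (1/n) sum_{p|n} mu(n/p) sigma^p for the aperiodic count.

#' Positive divisors of n, ascending
#' @keywords internal
divisors <- function(n) {
  stopifnot(n >= 1)
  d <- seq_len(n)
  d[n %% d == 0]
}

#' Euler's totient function
#'
#' Counts the integers in `[p] = {0, ..., p-1}` that are coprime to `p`
#' (0 counts for p = 1 by the usual convention phi(1) = 1).
#'
#' @param p positive integer.
#' @return a plain integer-valued numeric.
#' @examples
#' euler_totient(12) # 4
#' @export
euler_totient <- function(p) {
  stopifnot(length(p) == 1L, is.numeric(p), p == trunc(p))
  if (p < 1) stop("euler_totient: p must be a positive integer")
  res <- p
  m <- p
  f <- 2
  while (f * f <= m) {
    if (m %% f == 0) {
      res <- res / f * (f - 1)
      while (m %% f == 0) m <- m / f
    }
    f <- f + 1
  }
  if (m > 1) res <- res / m * (m - 1)
  res
}

#' Moebius function
#'
#' 0 when a square > 1 divides `n`, otherwise (-1)^q where q is the number
#' of distinct prime factors.
#'
#' @param n positive integer.
#' @return -1, 0 or 1.
#' @examples
#' mobius(30) # -1
#' @export
mobius <- function(n) {
  stopifnot(length(n) == 1L, is.numeric(n), n == trunc(n))
  if (n < 1) stop("mobius: n must be a positive integer")
  q <- 0L
  m <- n
  f <- 2
  while (f * f <= m) {
    if (m %% f == 0) {
      m <- m / f
      if (m %% f == 0) return(0L)
      q <- q + 1L
    } else {
      f <- f + 1
    }
  }
  if (m > 1) q <- q + 1L
  if (q %% 2L == 0L) 1L else -1L
}

#' Number of necklaces of length n over a sigma-letter alphabet
#'
#' @param sigma alphabet size (>= 1).
#' @param n necklace length (>= 1).
#' @return exact count as a [bigint][as_bigint].
#' @examples
#' as.numeric(necklace_count(2, 4)) # 6
#' @export
necklace_count <- function(sigma, n) {
  stopifnot(sigma >= 1, n >= 1)
  acc <- as_bigint(0)
  for (p in divisors(n)) {
    acc <- bn_add(acc, bn_mul_small(bn_pow(sigma, p), euler_totient(n / p)))
  }
  dm <- bn_divmod_small(acc, n)
  if (dm$r != 0) stop("internal error: necklace sum not divisible by n")
  dm$q
}

#' Number of aperiodic necklaces (Lyndon classes) of length n
#'
#' An aperiodic necklace is one whose n rotations are all distinct;
#' the count follows from the necklace formula by Moebius inversion.
#'
#' @inheritParams necklace_count
#' @return exact count as a [bigint][as_bigint].
#' @examples
#' as.numeric(aperiodic_necklace_count(2, 4)) # 3
#' @export
aperiodic_necklace_count <- function(sigma, n) {
  stopifnot(sigma >= 1, n >= 1)
  acc <- as_bigint(0)
  for (p in divisors(n)) {
    mu <- mobius(n / p)
    if (mu != 0) acc <- bn_add(acc, bn_mul_small(bn_pow(sigma, p), mu))
  }
  dm <- bn_divmod_small(acc, n)
  if (dm$r != 0) stop("internal error: aperiodic sum not divisible by n")
  dm$q
}

#' Lexicographically least rotation of a string
#'
#' Accepts either a character scalar or an integer symbol vector; the result
#' has the same type.  Symbol order for character input is the natural
#' single-character order ("0" < "1", "A" < "C" < "G" < "T").
#'
#' @param s nonempty string or integer vector.
#' @return the canonical (least) rotation, same representation as the input.
#' @examples
#' canonical_rotation("1001") # "0011"
#' @export
canonical_rotation <- function(s) {
  if (is.character(s)) {
    stopifnot(length(s) == 1L)
    v <- strsplit(s, "")[[1]]
    if (length(v) == 0L) stop("canonical_rotation: empty string")
    return(paste(.least_rotation(v), collapse = ""))
  }
  if (length(s) == 0L) stop("canonical_rotation: empty string")
  .least_rotation(s)
}

# O(n^2) least-rotation scan; n is always small here.
.least_rotation <- function(v) {
  n <- length(v)
  best <- v
  for (r in seq_len(n - 1L)) {
    cand <- v[c((r + 1L):n, 1L:r)]
    for (i in seq_len(n)) {
      if (cand[i] < best[i]) { best <- cand; break }
      if (cand[i] > best[i]) break
    }
  }
  best
}

#' Enumerate the pure cycles (necklaces) of the order-n De Bruijn graph
#'
#' The sigma^n strings of length n partition into pure cycles, one per
#' necklace; a cycle's length is the primitive period of its strings.  Each
#' cycle is returned as a `pure_cycle` object with fields `canonical`
#' (integer symbol vector, least rotation), `length`, `order` (= n) and
#' `vertices` (integer encodings of the cycle's strings, most significant
#' symbol first).
#'
#' @param sigma alphabet size.
#' @param n string length (De Bruijn graph order).
#' @param budget refuse when sigma^n exceeds this (default 1e7): the
#'   enumeration exists to serve exact density checks and ILP cuts at small
#'   scale.
#' @return list of `pure_cycle` objects.
#' @examples
#' length(enumerate_pure_cycles(2, 4)) # 6
#' @export
enumerate_pure_cycles <- function(sigma, n, budget = 1e7) {
  stopifnot(sigma >= 1, n >= 1)
  total <- sigma^n
  if (total > budget) {
    stop(sprintf("enumerate_pure_cycles: sigma^n = %g exceeds budget %g; raise `budget` only if you really want full enumeration", total, budget))
  }
  visited <- logical(total)
  pows <- sigma^(seq_len(n) - 1L) # little-endian powers
  cycles <- list()
  for (e in 0:(total - 1)) {
    if (visited[e + 1]) next
    digits <- (e %/% pows) %% sigma          # digits[i] = symbol at position n-i (LSB first)
    word <- rev(digits)                      # most significant first
    # walk rotations
    verts <- numeric(n)
    cur <- word
    len <- 0L
    repeat {
      enc <- sum(cur * rev(pows))
      if (visited[enc + 1]) break
      visited[enc + 1] <- TRUE
      len <- len + 1L
      verts[len] <- enc
      cur <- c(cur[-1L], cur[1L])
    }
    cycles[[length(cycles) + 1L]] <- structure(
      list(canonical = as.integer(.least_rotation(word)),
           length = len, order = as.integer(n),
           vertices = verts[seq_len(len)]),
      class = "pure_cycle")
  }
  cycles
}

#' @export
print.pure_cycle <- function(x, ...) {
  cat(sprintf("<pure_cycle> order %d, length %d, canonical %s\n",
              x$order, x$length, paste(x$canonical, collapse = "")))
  invisible(x)
}
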