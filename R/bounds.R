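# Necklace-based lower bounds on sampling scheme density.
#
# For a (w,k)-forward scheme the density is at least
#   g_sigma(w,k) = (1/sigma^(w+k)) * sum_{p | w+k} M_sigma(p) * ceil(p/w),
# where M_sigma counts aperiodic necklaces: the charged contexts of a scheme
# form a (w, w+k)-universal hitting set, and every pure cycle of length p in
# the order-(w+k) De Bruijn graph must contribute at least ceil(p/w) hits.
# The improved bound g' additionally evaluates g at the smallest k' >= k
# with k' = 1 (mod w), where g has its local maxima, and takes the max.
# Everything is carried as an exact big-integer fraction; floats are for
# display.

.new_bound_result <- function(w, k, sigma, kind, num, den, k_prime = NA_integer_) {
  structure(list(
    w = w, k = k, sigma = sigma, kind = kind,
    num = num, den = den,
    value = bn_ratio(num, den),
    k_prime = k_prime
  ), class = "bound_result")
}

#' @export
print.bound_result <- function(x, digits = 3, ...) {
  kp <- if (!is.na(x$k_prime)) sprintf(" (k' = %d)", x$k_prime) else ""
  cat(sprintf("<bound_result %s> sigma=%d w=%d k=%d%s\n  %s / %s = %.*f\n",
              x$kind, x$sigma, x$w, x$k, kp,
              as.character(x$num), as.character(x$den), digits, x$value))
  invisible(x)
}

.check_swk <- function(sigma, w, k) {
  stopifnot(sigma >= 2, w >= 1, k >= 1,
            sigma == trunc(sigma), w == trunc(w), k == trunc(k))
}

#' Necklace lower bound g on forward scheme density
#'
#' Computes `g_sigma(w, k) = sum_{p | w+k} M_sigma(p) ceil(p/w) / sigma^(w+k)`
#' exactly.  It always dominates the simple bound `ceil((w+k)/w)/(w+k)`,
#' which in turn dominates the trivial window-guarantee bound `1/w`.
#'
#' @param sigma alphabet size (>= 2).
#' @param w window guarantee (>= 1).
#' @param k k-mer length (>= 1).
#' @return a `bound_result` with exact numerator/denominator and float value.
#' @examples
#' lower_bound_g(2, 4, 2) # 23/64
#' @export
lower_bound_g <- function(sigma, w, k) {
  .check_swk(sigma, w, k)
  n <- w + k
  num <- as_bigint(0)
  for (p in divisors(n)) {
    num <- bn_add(num, bn_mul_small(aperiodic_necklace_count(sigma, p), ceiling(p / w)))
  }
  .new_bound_result(w, k, sigma, "g", num, bn_pow(sigma, n))
}

# smallest k' >= k with k' = 1 (mod w)
.k_prime <- function(w, k) as.integer(k + ((1 - k) %% w))

#' Improved lower bound g' on forward scheme density
#'
#' `g'_sigma(w,k) = max(g_sigma(w,k), g_sigma(w,k'))` where `k'` is the
#' smallest integer >= k congruent to 1 mod w.  Valid because a (w,k)-scheme
#' can be lifted to any k'' > k with identical density by ignoring trailing
#' characters, so any lower bound at k' also binds at k.
#'
#' @inheritParams lower_bound_g
#' @return a `bound_result`; `$k_prime` records the k' used.
#' @examples
#' lower_bound_g_prime(4, 19, 19) # 0.077 at 3 decimals, k' = 20
#' @export
lower_bound_g_prime <- function(sigma, w, k) {
  .check_swk(sigma, w, k)
  kp <- .k_prime(w, k)
  g1 <- lower_bound_g(sigma, w, k)
  if (kp == k) {
    best <- g1
  } else {
    g2 <- lower_bound_g(sigma, w, kp)
    # compare num1/den1 vs num2/den2 by cross-multiplication, exactly
    lhs <- bn_mul(g1$num, g2$den)
    rhs <- bn_mul(g2$num, g1$den)
    best <- if (bn_cmp(lhs, rhs) >= 0L) g1 else g2
  }
  .new_bound_result(w, k, sigma, "g_prime", best$num, best$den, k_prime = kp)
}

#' Simple approximate lower bound ceil((w+k)/w)/(w+k)
#'
#' @param w window guarantee.
#' @param k k-mer length.
#' @return a `bound_result` (kind `"simple"`).
#' @export
simple_bound <- function(w, k) {
  stopifnot(w >= 1, k >= 1)
  .new_bound_result(w, k, NA_integer_, "simple",
                    as_bigint(ceiling((w + k) / w)), as_bigint(w + k))
}

#' Earlier lower bound 1.5/(w+k-0.5), for comparison only
#'
#' @inheritParams simple_bound
#' @return a float.
#' @export
prior_bound <- function(w, k) {
  stopifnot(w >= 1, k >= 1)
  1.5 / (w + k - 0.5)
}

#' Lower bound on the size of a (w, l)-universal hitting set
#'
#' `sum_{p | l} M_sigma(p) ceil(p/w)`: the pure cycles of the order-l
#' De Bruijn graph partition its vertices, and a (w,l)-UHS must hit every
#' cycle of length p at least ceil(p/w) times.  Cycles shorter than the
#' window (p < w) still contribute ceil(p/w) = 1, as the formula states.
#'
#' @param sigma alphabet size (>= 2).
#' @param w window size (>= 2).
#' @param ell l-mer length (>= 1).
#' @return exact count as a [bigint][as_bigint].
#' @examples
#' as.numeric(uhs_lower_bound(2, 2, 4)) # 9
#' @export
uhs_lower_bound <- function(sigma, w, ell) {
  stopifnot(sigma >= 2, w >= 2, ell >= 1)
  acc <- as_bigint(0)
  for (p in divisors(ell)) {
    acc <- bn_add(acc, bn_mul_small(aperiodic_necklace_count(sigma, p), ceiling(p / w)))
  }
  acc
}

#' Lower bound on local scheme density
#'
#' A (w,k)-local scheme's charged contexts have length 2w+k-2 and form a
#' (w, 2w+k-2)-UHS, so its density is bounded below by g'_sigma(w, w+k-2).
#'
#' @inheritParams lower_bound_g
#' @return a `bound_result` (kind `"local"`).
#' @export
local_scheme_bound <- function(sigma, w, k) {
  stopifnot(sigma >= 2, w >= 2, k >= 1)
  k2 <- w + k - 2
  if (k2 < 1) stop("local_scheme_bound: w + k - 2 must be >= 1")
  r <- lower_bound_g_prime(sigma, w, k2)
  .new_bound_result(w, k, sigma, "local", r$num, r$den, k_prime = r$k_prime)
}

#' Asymptotic density of the mod-minimizer for large alphabets
#'
#' When k = 1 (mod w) and sigma grows, the mod-minimizer with t = 1 attains
#' density `(floor((w+k-2)/w) + 2) / (w+k)`, which under that congruence
#' equals the simple bound `ceil((w+k)/w)/(w+k)` -- i.e. the scheme is
#' asymptotically optimal there.
#'
#' @inheritParams simple_bound
#' @return a `bound_result` (kind `"mod_asymptotic"`).
#' @export
mod_minimizer_asymptotic_density <- function(w, k) {
  stopifnot(w >= 1, k >= 1)
  if ((k - 1) %% w != 0) {
    stop("mod_minimizer_asymptotic_density: requires k = 1 (mod w)")
  }
  .new_bound_result(w, k, NA_integer_, "mod_asymptotic",
                    as_bigint(floor((w + k - 2) / w) + 2), as_bigint(w + k))
}
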