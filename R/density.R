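# Density of sampling schemes, exactly and empirically.
#
# The density of a scheme is the expected proportion of sampled k-mer
# positions in an infinite uniform random string.  It equals the proportion
# of *charged contexts*: strings just long enough that the scheme's choice
# on their last window determines whether a new position is sampled.  For a
# forward scheme a context is two overlapping windows (length w+k, one edge
# of the De Bruijn graph B_{w+k-1}); it is charged when
# f(W[0, w+k-1)) != f(W[1, w+k)) + 1.  For a local scheme the context spans
# the w-1 preceding windows too (length 2w+k-2) and is charged when the last
# window's absolute pick differs from every earlier window's pick.

.enum_budget_check <- function(n, budget, what) {
  if (n > budget) {
    stop(sprintf("%s needs %g contexts, above the enumeration budget %g; raise `budget` to force it", what, n, budget))
  }
}

# rule values for all sigma^(w+k-1) windows, indexed by encoding + 1
.window_rule_values <- function(scheme) {
  if (!is.null(scheme$table)) return(scheme$table)
  w <- scheme$w; k <- scheme$k; sigma <- scheme$sigma
  n <- sigma^(w + k - 1)
  f <- integer(n)
  for (e in 0:(n - 1)) {
    f[e + 1L] <- scheme$rule(int_to_digits(e, w + k - 1L, sigma))
  }
  f
}

.new_context_set <- function(scheme, mode, ell, members, n_total) {
  structure(list(scheme = scheme, mode = mode, ell = as.integer(ell),
                 sigma = scheme$sigma, members = members,
                 n_total = n_total),
            class = "charged_context_set")
}

#' @export
print.charged_context_set <- function(x, ...) {
  cat(sprintf("<charged_context_set %s> %d of %g contexts of length %d charged (density %.6f)\n",
              x$mode, length(x$members), x$n_total, x$ell,
              length(x$members) / x$n_total))
  invisible(x)
}

#' Charged contexts of a forward scheme
#'
#' Enumerates all sigma^(w+k) contexts and keeps those whose two window
#' evaluations disagree with a simple forward step.  The returned set is a
#' (w, w+k)-universal hitting set for any valid scheme.
#'
#' @param scheme a `scheme_spec`.
#' @param budget refuse when sigma^(w+k) exceeds this.
#' @return a `charged_context_set` whose `members` are integer context
#'   encodings (most significant symbol first).
#' @export
charged_contexts_forward <- function(scheme, budget = 1e7) {
  stopifnot(inherits(scheme, "scheme_spec"))
  w <- scheme$w; k <- scheme$k; sigma <- scheme$sigma
  n <- sigma^(w + k)
  .enum_budget_check(n, budget, "charged_contexts_forward")
  f <- .window_rule_values(scheme)
  ctx <- 0:(n - 1)
  nu <- sigma^(w + k - 1)
  u <- ctx %/% sigma        # first w+k-1 symbols
  v <- ctx %% nu            # last  w+k-1 symbols
  charged <- f[u + 1L] != f[v + 1L] + 1L
  .new_context_set(scheme, "forward", w + k, ctx[charged], n)
}

#' Charged contexts of a scheme in local mode
#'
#' Contexts have length 2w+k-2 (the current window plus the w-1 preceding
#' ones); a context is charged when the last window's absolute selection
#' `f(last) + (w-1)` differs from `f(window_i) + i` for every earlier offset
#' `i` in 0..w-2.  For a forward scheme this count gives the same density as
#' the forward-mode enumeration.
#'
#' @inheritParams charged_contexts_forward
#' @export
charged_contexts_local <- function(scheme, budget = 1e7) {
  stopifnot(inherits(scheme, "scheme_spec"))
  w <- scheme$w; k <- scheme$k; sigma <- scheme$sigma
  ell <- 2L * w + k - 2L
  n <- sigma^ell
  .enum_budget_check(n, budget, "charged_contexts_local")
  f <- .window_rule_values(scheme)
  ctx <- 0:(n - 1)
  nwid <- sigma^(w + k - 1)
  charged <- rep(TRUE, n)
  # window at offset i covers symbols i .. i+w+k-2 of the context
  wlast <- (ctx %/% sigma^(ell - (w - 1L) - (w + k - 1L))) %% nwid
  xlast <- f[wlast + 1L] + (w - 1L)
  if (w >= 2L) {
    for (i in 0:(w - 2L)) {
      wi <- (ctx %/% sigma^(ell - i - (w + k - 1L))) %% nwid
      charged <- charged & (xlast != f[wi + 1L] + i)
    }
  }
  .new_context_set(scheme, "local", ell, ctx[charged], n)
}

.new_density <- function(value, n, mode, charged = NA, total = NA) {
  structure(list(value = value, n = n, mode = mode,
                 charged = charged, total = total),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  extra <- if (x$mode == "exact") sprintf(" (= %g/%g)", x$charged, x$total) else ""
  cat(sprintf("<density_estimate %s> %.6f%s over %g %s\n", x$mode, x$value, extra,
              x$n, if (x$mode == "exact") "contexts" else "k-mer positions"))
  invisible(x)
}

#' Exact scheme density by charged-context enumeration
#'
#' @param scheme a `scheme_spec`.
#' @param mode `"forward"` (contexts of length w+k; valid for forward
#'   schemes) or `"local"` (length 2w+k-2; valid for any local scheme).
#' @param budget enumeration budget.
#' @return a `density_estimate` with the exact fraction.
#' @export
exact_density <- function(scheme, mode = c("forward", "local"), budget = 1e7) {
  mode <- match.arg(mode)
  cs <- if (mode == "forward") charged_contexts_forward(scheme, budget)
        else charged_contexts_local(scheme, budget)
  .new_density(length(cs$members) / cs$n_total, cs$n_total, "exact",
               charged = length(cs$members), total = cs$n_total)
}

#' Empirical scheme density on a sequence
#'
#' Applies the scheme to every window and reports the number of distinct
#' selected positions divided by the number of k-mer positions
#' (|S| - k + 1).  The window-count denominator would differ by O(w/|S|).
#'
#' @param scheme a `scheme_spec`.
#' @param sequence symbol vector or string (see [encode_sequence]).
#' @export
empirical_density <- function(scheme, sequence) {
  seq <- encode_sequence(sequence, scheme$sigma)
  if (length(seq) < scheme$w + scheme$k - 1L) {
    stop("sequence shorter than one window")
  }
  pos <- select_positions(scheme, seq)
  nk <- length(seq) - scheme$k + 1L
  .new_density(length(pos) / nk, nk, "empirical")
}

#' Check that a scheme is forward
#'
#' Exhaustively verifies `f(W[0, w+k-1)) <= f(W[1, w+k)) + 1` over all
#' contexts of length w+k; when the inequality fails the first violating
#' context is returned as a witness.
#'
#' @param scheme a `scheme_spec`.
#' @param budget enumeration budget; above it, a seeded random sample of
#'   contexts is checked instead (with a warning).
#' @param sample_size number of sampled contexts in the fallback mode.
#' @return list with `forward` (logical) and `counterexample` (integer
#'   symbol vector of length w+k, or NULL).
#' @export
is_forward <- function(scheme, budget = 1e7, sample_size = 1e5) {
  stopifnot(inherits(scheme, "scheme_spec"))
  w <- scheme$w; k <- scheme$k; sigma <- scheme$sigma
  n <- sigma^(w + k)
  if (n <= budget) {
    f <- .window_rule_values(scheme)
    ctx <- 0:(n - 1)
    nu <- sigma^(w + k - 1)
    bad <- which(f[ctx %/% sigma + 1L] > f[ctx %% nu + 1L] + 1L)
    if (length(bad) == 0L) return(list(forward = TRUE, counterexample = NULL))
    return(list(forward = FALSE,
                counterexample = int_to_digits(ctx[bad[1L]], w + k, sigma)))
  }
  warning("context space above budget; falling back to sampled forwardness check")
  span <- w + k
  for (i in seq_len(sample_size)) {
    ctx <- sample.int(sigma, span, replace = TRUE) - 1L
    a <- scheme$rule(ctx[1:(span - 1L)])
    b <- scheme$rule(ctx[2:span])
    if (a > b + 1L) return(list(forward = FALSE, counterexample = ctx))
  }
  list(forward = TRUE, counterexample = NULL)
}

#' Verify the universal hitting set property
#'
#' A set of l-mers is a (w, l)-UHS when every string of length l+w-1 (i.e.
#' every walk of w consecutive l-mers in the De Bruijn graph B_l) contains a
#' member.  Checked by full enumeration.
#'
#' @param x a `charged_context_set`, or a numeric vector of l-mer encodings.
#' @param w window size.
#' @param sigma,ell alphabet size and l-mer length (taken from `x` when it
#'   is a `charged_context_set`).
#' @param budget enumeration budget for sigma^(ell+w-1).
#' @return TRUE or FALSE.
#' @export
verify_uhs <- function(x, w, sigma = NULL, ell = NULL, budget = 1e7) {
  if (inherits(x, "charged_context_set")) {
    sigma <- x$sigma; ell <- x$ell; members <- x$members
  } else {
    stopifnot(!is.null(sigma), !is.null(ell))
    members <- x
  }
  stopifnot(w >= 1)
  n_l <- sigma^ell
  .enum_budget_check(n_l, budget, "verify_uhs (member table)")
  n_s <- sigma^(ell + w - 1)
  .enum_budget_check(n_s, budget, "verify_uhs (walk enumeration)")
  memb <- logical(n_l)
  memb[members + 1] <- TRUE
  s <- 0:(n_s - 1)
  hit <- rep(FALSE, n_s)
  for (i in 0:(w - 1)) {
    enc <- (s %/% sigma^(w - 1 - i)) %% n_l
    hit <- hit | memb[enc + 1]
  }
  all(hit)
}
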