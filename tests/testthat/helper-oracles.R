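# Brute-force oracles, kept deliberately independent of the implementation
# paths they check.

oracle_gcd <- function(a, b) {
  while (b != 0) { t <- a %% b; a <- b; b <- t }
  a
}

# totient by direct coprimality count
oracle_totient <- function(p) {
  if (p == 1) return(1)
  sum(vapply(0:(p - 1), function(i) oracle_gcd(i, p) == 1, logical(1)))
}

# Moebius by explicit trial-division factorization
oracle_mobius <- function(n) {
  if (n == 1) return(1L)
  q <- 0L
  for (f in 2:n) {
    if (n %% f == 0) {
      n <- n %/% f
      if (n %% f == 0) return(0L)
      q <- q + 1L
    }
    if (f > n) break
  }
  if (q %% 2L == 0L) 1L else -1L
}

# group all sigma^n strings by rotation class; returns class sizes
oracle_rotation_classes <- function(sigma, n) {
  total <- sigma^n
  seen <- logical(total)
  sizes <- integer(0)
  for (e in 0:(total - 1)) {
    if (seen[e + 1]) next
    d <- int_to_digits(e, n, sigma)
    size <- 0L
    cur <- d
    repeat {
      enc <- digits_to_int(cur, sigma)
      if (seen[enc + 1]) break
      seen[enc + 1] <- TRUE
      size <- size + 1L
      cur <- c(cur[-1], cur[1])
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# sliding-window simulation: fraction of windows that select a new position,
# evaluated through the scheme's own per-window rule (not select_positions)
oracle_sliding_density <- function(scheme, seq) {
  span <- scheme$w + scheme$k - 1L
  nwin <- length(seq) - span + 1L
  seen <- logical(length(seq))
  new_events <- 0L
  for (j in seq_len(nwin)) {
    pos <- (j - 1L) + scheme$rule(seq[j:(j + span - 1L)])
    if (!seen[pos + 1L]) { seen[pos + 1L] <- TRUE; new_events <- new_events + 1L }
  }
  new_events / nwin
}

# charged-context count obtained by walking every pure cycle of B_{w+k}
oracle_cycle_walk_charged <- function(scheme) {
  w <- scheme$w; k <- scheme$k; sigma <- scheme$sigma
  cycles <- enumerate_pure_cycles(sigma, w + k)
  charged <- 0L
  for (cy in cycles) {
    for (enc in cy$vertices) {
      ctx <- int_to_digits(enc, w + k, sigma)
      a <- scheme$rule(ctx[1:(w + k - 1)])
      b <- scheme$rule(ctx[2:(w + k)])
      if (a != b + 1L) charged <- charged + 1L
    }
  }
  charged
}

# all built-in hash-based schemes valid at the given parameters
builtin_schemes <- function(w, k, sigma, seed = 1) {
  out <- list(
    random = random_minimizer(w, k, sigma, seed = seed),
    lexicographic = lexicographic_minimizer(w, k, sigma),
    mod = mod_minimizer(w, k, sigma, seed = seed),
    miniception = miniception(w, k, sigma, seed = seed, t = max(1, min(k, 2)))
  )
  if (k >= 2) out$double_decycling <- double_decycling_minimizer(w, k, sigma, seed = seed)
  out
}
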