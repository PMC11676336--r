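# Sampling schemes as window -> index rules.
#
# A (w,k)-local scheme is a total function from windows of w+k-1 symbols to
# an index in [w] = {0, ..., w-1}: the window's sampled k-mer.  Every scheme
# here is represented by a `scheme_spec` whose `rule` closure evaluates one
# window (an integer symbol vector over [sigma]); the built-in schemes
# additionally carry a `scheme_id` that routes long-sequence evaluation to
# the compiled path, which shares the same chooser code.
#
# Alphabet convention: symbols are always integers 0..sigma-1 internally;
# DNA maps A->0, C->1, G->2, T->3.

DNA_SYMBOLS <- c(A = 0L, C = 1L, G = 2L, T = 3L)

.new_scheme <- function(name, w, k, sigma, params, scheme_id, rule, table = NULL) {
  stopifnot(w >= 1, k >= 1, sigma >= 2)
  structure(list(name = name, w = as.integer(w), k = as.integer(k),
                 sigma = as.integer(sigma), params = params,
                 scheme_id = scheme_id, rule = rule, table = table),
            class = "scheme_spec")
}

#' @export
print.scheme_spec <- function(x, ...) {
  p <- if (length(x$params)) paste0(", ", paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")) else ""
  cat(sprintf("<scheme_spec %s> w=%d k=%d sigma=%d%s\n", x$name, x$w, x$k, x$sigma, p))
  invisible(x)
}

.check_window <- function(window, w, k, sigma) {
  if (length(window) != w + k - 1) stop("window must have length w + k - 1")
  if (any(window < 0 | window >= sigma)) stop("window symbols must lie in [sigma]")
}

#' Random minimizer scheme
#'
#' Samples the k-mer with the smallest seeded 64-bit hash in each window;
#' ties broken by the k-mer itself, then leftmost.  Expected density on
#' random sequences is approximately 2/(w+1) for k not much smaller than
#' log_sigma(w).
#'
#' @param w window guarantee.
#' @param k k-mer length.
#' @param sigma alphabet size.
#' @param seed hash seed (any non-negative integer below 2^53).
#' @return a `scheme_spec`.
#' @export
random_minimizer <- function(w, k, sigma, seed = 1) {
  force(w); force(k); force(sigma); force(seed)
  .new_scheme("random", w, k, sigma, list(seed = seed), 1L,
              function(window) {
                .check_window(window, w, k, sigma)
                cpp_scheme_index(as.integer(window), w, k, 1L, seed, 0L)
              })
}

#' Lexicographic minimizer scheme
#'
#' As [random_minimizer] but ordered by the k-mer's own lexicographic value
#' rather than a hash.  Deterministic; mainly useful as a teaching and
#' oracle scheme in tests.
#'
#' @inheritParams random_minimizer
#' @export
lexicographic_minimizer <- function(w, k, sigma) {
  force(w); force(k); force(sigma)
  .new_scheme("lexicographic", w, k, sigma, list(), 2L,
              function(window) {
                .check_window(window, w, k, sigma)
                cpp_scheme_index(as.integer(window), w, k, 2L, 0, 0L)
              })
}

#' Mod-minimizer scheme
#'
#' Finds the leftmost-minimal t-mer (by seeded hash) among the w+k-t t-mers
#' of the window, at position p, and samples the k-mer at position p mod w.
#' The default parameter choice is the smallest t >= r with t = k (mod w)
#' (r = 4), capped at k; t = 1 is a useful override for large alphabets,
#' where the scheme approaches the density lower bound when k = 1 (mod w).
#'
#' @inheritParams random_minimizer
#' @param r minimum t-mer size used when choosing t automatically.
#' @param t explicit t-mer size override (1 <= t <= k).
#' @export
mod_minimizer <- function(w, k, sigma, seed = 1, r = 4, t = NULL) {
  if (is.null(t)) {
    t <- r + ((k - r) %% w)
    if (t > k) t <- k
  }
  stopifnot(t >= 1, t <= k)
  t <- as.integer(t)
  force(w); force(k); force(sigma); force(seed)
  .new_scheme("mod_minimizer", w, k, sigma, list(seed = seed, r = r, t = t), 3L,
              function(window) {
                .check_window(window, w, k, sigma)
                cpp_scheme_index(as.integer(window), w, k, 3L, seed, t)
              })
}

#' Miniception scheme
#'
#' A k-mer is "preferred" when the leftmost-minimal t-mer inside it (by
#' seeded hash) sits at offset 0 or k-t.  Among the preferred k-mers of the
#' window the scheme picks the one minimal by k-mer hash (leftmost on ties);
#' when no k-mer is preferred it falls back to the plain random-minimizer
#' choice.  Default t is max(4, k-w).
#'
#' @inheritParams mod_minimizer
#' @export
miniception <- function(w, k, sigma, seed = 1, t = NULL) {
  if (is.null(t)) t <- max(4, k - w)
  if (t < 1 || t > k) stop("miniception: t must satisfy 1 <= t <= k")
  t <- as.integer(t)
  force(w); force(k); force(sigma); force(seed)
  .new_scheme("miniception", w, k, sigma, list(seed = seed, t = t), 4L,
              function(window) {
                .check_window(window, w, k, sigma)
                cpp_scheme_index(as.integer(window), w, k, 4L, seed, t)
              })
}

#' Double-decycling minimizer scheme
#'
#' Orders k-mers by (class, hash, k-mer, leftmost) where the class comes
#' from the Mykkeltveit complex-plane embedding
#' `P(u) = sum_j u_j exp(2 pi i j / k)`: class 0 if `P != 0`, `Im(P) <= 0`
#' and `Im(P omega) > 0` with `omega = exp(2 pi i / k)` -- Mykkeltveit's
#' crossing rule, selecting the rotation whose embedding is about to cross
#' the positive real axis (a decycling set); class 1 the same for `-P` (the
#' mirrored decycling set); class 2 otherwise (including `P == 0`, e.g.
#' homopolymers).  At most one rotation of an aperiodic k-mer lands in
#' class 0, since rotating shifts `arg(P)` by `2 pi / k`.
#'
#' @inheritParams random_minimizer
#' @export
double_decycling_minimizer <- function(w, k, sigma, seed = 1) {
  stopifnot(k >= 2)
  force(w); force(k); force(sigma); force(seed)
  .new_scheme("double_decycling", w, k, sigma, list(seed = seed), 5L,
              function(window) {
                .check_window(window, w, k, sigma)
                cpp_scheme_index(as.integer(window), w, k, 5L, seed, 0L)
              })
}

#' Table-backed scheme
#'
#' A scheme given explicitly as a lookup table over all sigma^(w+k-1)
#' windows, indexed by the window's integer encoding (most significant
#' symbol first).  This is the carrier for ILP solutions and hand-built
#' schemes.
#'
#' @inheritParams random_minimizer
#' @param table integer vector of length sigma^(w+k-1), entries in 0..w-1.
#' @export
table_scheme <- function(w, k, sigma, table) {
  n <- sigma^(w + k - 1)
  if (length(table) != n) {
    stop(sprintf("table must have exactly sigma^(w+k-1) = %d entries", n))
  }
  table <- as.integer(round(table))
  if (any(table < 0L | table >= w)) stop("table entries must lie in [w]")
  force(w); force(k); force(sigma)
  .new_scheme("table", w, k, sigma, list(), 0L,
              function(window) {
                .check_window(window, w, k, sigma)
                table[digits_to_int(window, sigma) + 1L]
              },
              table = table)
}

#' Integer encoding of a symbol vector (most significant symbol first)
#' @param digits integer vector over [sigma].
#' @param sigma alphabet size.
#' @export
digits_to_int <- function(digits, sigma) {
  v <- 0
  for (d in digits) v <- v * sigma + d
  v
}

#' Inverse of [digits_to_int]
#' @param e non-negative integer encoding.
#' @param len number of symbols.
#' @param sigma alphabet size.
#' @export
int_to_digits <- function(e, len, sigma) {
  d <- integer(len)
  for (i in rev(seq_len(len))) {
    d[i] <- e %% sigma
    e <- e %/% sigma
  }
  d
}

#' Convert a sequence to internal integer symbols
#'
#' Accepts an integer vector over `[sigma]` (returned unchanged after
#' validation), a DNA string over ACGT (sigma = 4; A->0, C->1, G->2, T->3),
#' or a digit string over 0..sigma-1.
#'
#' @param x sequence.
#' @param sigma alphabet size.
#' @export
encode_sequence <- function(x, sigma) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (length(x) && (min(x) < 0L || max(x) >= sigma)) {
      stop("sequence symbols must lie in [sigma]")
    }
    return(x)
  }
  stopifnot(is.character(x), length(x) == 1L)
  ch <- strsplit(toupper(x), "")[[1]]
  if (sigma == 4 && all(ch %in% names(DNA_SYMBOLS))) {
    return(unname(DNA_SYMBOLS[ch]))
  }
  v <- suppressWarnings(as.integer(ch))
  if (anyNA(v) || (length(v) && (min(v) < 0L || max(v) >= sigma))) {
    stop("sequence contains symbols outside the alphabet; see read_fasta() policies for DNA input")
  }
  v
}

#' Apply a scheme to a sequence
#'
#' Slides the scheme over every window of the sequence and returns the
#' sorted, de-duplicated 0-based start positions of the sampled k-mers.
#' For any scheme the gap between consecutive selected positions is at most
#' w (the window guarantee).
#'
#' @param scheme a `scheme_spec`.
#' @param sequence integer symbol vector over `[sigma]` or a string (see
#'   [encode_sequence]).
#' @return integer vector of selected positions (possibly empty, with a
#'   warning, when the sequence is shorter than one window).
#' @export
select_positions <- function(scheme, sequence) {
  stopifnot(inherits(scheme, "scheme_spec"))
  seq <- encode_sequence(sequence, scheme$sigma)
  span <- scheme$w + scheme$k - 1L
  if (length(seq) < span) {
    warning("sequence shorter than one window; no positions selected")
    return(integer(0))
  }
  if (scheme$scheme_id > 0L) {
    return(cpp_select_positions(seq, scheme$w, scheme$k, scheme$scheme_id,
                                .scheme_seed(scheme), .scheme_t(scheme)))
  }
  nwin <- length(seq) - span + 1L
  sel <- integer(nwin)
  for (j in seq_len(nwin)) {
    sel[j] <- (j - 1L) + scheme$rule(seq[j:(j + span - 1L)])
  }
  sort(unique(sel))
}

.scheme_seed <- function(scheme) {
  s <- scheme$params$seed
  if (is.null(s)) 0 else as.numeric(s)
}

.scheme_t <- function(scheme) {
  t <- scheme$params$t
  if (is.null(t)) 0L else as.integer(t)
}

#' Serialize a scheme to JSON
#'
#' Table schemes round-trip exactly; hash-based schemes serialize their
#' parameters (including the seed) and are reconstructed by name.
#'
#' @param scheme a `scheme_spec`.
#' @param path file path.
#' @export
write_scheme <- function(scheme, path) {
  obj <- list(name = scheme$name, w = scheme$w, k = scheme$k,
              sigma = scheme$sigma, params = scheme$params)
  if (!is.null(scheme$table)) obj$table <- scheme$table
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a scheme written by [write_scheme]
#' @param path file path.
#' @export
read_scheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- as.list(obj$params)
  switch(obj$name,
    table = table_scheme(obj$w, obj$k, obj$sigma, obj$table),
    random = random_minimizer(obj$w, obj$k, obj$sigma, seed = p$seed),
    lexicographic = lexicographic_minimizer(obj$w, obj$k, obj$sigma),
    mod_minimizer = mod_minimizer(obj$w, obj$k, obj$sigma, seed = p$seed, r = p$r, t = p$t),
    miniception = miniception(obj$w, obj$k, obj$sigma, seed = p$seed, t = p$t),
    double_decycling = double_decycling_minimizer(obj$w, obj$k, obj$sigma, seed = p$seed),
    stop("unknown scheme name: ", obj$name)
  )
}

#' Hex digest of the scheme hash order applied to a symbol vector
#'
#' Exposed for reproducibility checks: the same seed and symbols yield the
#' same 64-bit value on every platform.
#'
#' @param symbols integer symbol vector.
#' @param seed hash seed.
#' @export
hash_order_hex <- function(symbols, seed = 1) {
  cpp_hash64_hex(as.integer(symbols), as.numeric(seed))
}
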