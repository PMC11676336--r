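---
title: "Methods: density of k-mer sampling schemes, its lower bounds, and optimal scheme search"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A *(w, k)-local sampling scheme* is a function `f` from windows of
`w + k - 1` symbols (equivalently, `w` consecutive k-mers) to an index in
`[w] = {0, ..., w-1}`: the k-mer the window samples.  Such schemes carry a
*window guarantee* — at least one k-mer sampled out of every `w` consecutive
ones — which is what makes minimizer-type sketches usable for indexing and
alignment.  A scheme is *forward* when the sampled position never moves
backwards between adjacent windows (`f(W[0, w+k-1)) <= f(W[1, w+k)) + 1`);
all minimizer variants implemented here are forward.

The quality measure is the *density*: the expected proportion of sampled
k-mer positions in an infinite uniform random string.  Lower density means a
sparser sketch at the same guarantee.  This package computes densities
exactly and empirically, computes lower bounds on the best achievable
density, and searches for provably minimum-density schemes on small
parameter sets.

# Charged contexts and exact density

A window samples a *new* position exactly when its choice differs from what
the relevant preceding windows chose.  The shortest string that decides this
is the *context*: length `w + k` for forward schemes (two overlapping
windows; one edge of the De Bruijn graph `B_{w+k-1}`), and `2w + k - 2` for
general local schemes (the current window plus its `w - 1` predecessors).
A context whose last window samples a new position is *charged*, and the
density equals the fraction of charged contexts among all `sigma^ell`
contexts.  `exact_density()` enumerates them; two independent oracles (a
sliding-window simulation and a walk over every pure cycle of `B_{w+k}`)
are used in the test suite to confirm the enumeration.

Charged contexts are not just a counting device: for any valid scheme they
form a *(w, ell)-universal hitting set* — every walk of `w` consecutive
`ell`-mers contains a charged one — which `verify_uhs()` checks directly and
which underlies both the lower bound and the integer program below.

# The necklace lower bounds

The vertices of the De Bruijn graph `B_ell` partition into *pure cycles*
(necklaces); a cycle of length `p` must contribute at least `ceiling(p/w)`
members to any `(w, ell)`-UHS.  Counting cycles with the Moebius formula for
aperiodic necklaces `M_sigma(p)` gives the bound implemented in
`uhs_lower_bound()`, and dividing by `sigma^(w+k)` the density bound

    g_sigma(w, k) = sum_{p | w+k} M_sigma(p) * ceiling(p/w) / sigma^(w+k)
                 >= ceiling((w+k)/w) / (w+k)   >=   1/w .

`g` is not monotone in k, but a (w, k)-scheme can be lifted to any larger
k at identical density by ignoring trailing symbols, so the bound may be
evaluated at the smallest `k' >= k` with `k' = 1 (mod w)` — where its local
maxima sit — and maximized: that is `lower_bound_g_prime()`.  For local
schemes the same machinery applies with contexts of length `2w + k - 2`,
giving `local_scheme_bound(sigma, w, k) = g'_sigma(w, w+k-2)`.

All of this is integer arithmetic: `M_sigma(p)` reaches `2^128` at
`sigma = 256, p = 16`, far beyond exact double range.  Counts and bound
fractions are therefore carried in a small arbitrary-precision integer layer
(`R/bignum.R`, base-1e7 digit vectors); floats appear only at display time.
Rational comparisons (e.g. which of `g(w,k)` and `g(w,k')` is larger) are
done by cross-multiplication of big integers, never in floating point.

# The scheme implementations

All schemes share one total order on strings: a seeded splitmix64 hash
(`h = seed; h = splitmix64(h XOR (symbol+1))` per symbol), with ties broken
by the string itself and then by the leftmost position.  The constants are
fixed, so results are bit-reproducible across platforms; the same C++
chooser evaluates single windows (for exact enumeration) and whole
sequences (for empirical density), so the two paths cannot drift apart.

* `random_minimizer()` — classic minimizer under the hash order; density
  near `2/(w+1)` for typical parameters.
* `lexicographic_minimizer()` — identity order; deterministic oracle scheme.
* `mod_minimizer()` — finds the minimal t-mer at position `p` in the window
  and samples the k-mer at `p mod w`.  `t` defaults to the smallest value
  `>= r` (r = 4) congruent to `k mod w`, capped at `k`; `t = 1` is exposed
  for large alphabets, where duplicate t-mers vanish and the scheme
  approaches the lower bound whenever `k = 1 (mod w)`.
* `miniception()` — a k-mer is *preferred* when its leftmost-minimal t-mer
  sits at offset 0 or `k - t`; the minimal preferred k-mer is sampled,
  falling back to the plain minimizer choice when none is preferred.
  `t` defaults to `max(4, k - w)`.
* `double_decycling_minimizer()` — ranks k-mers by membership in
  Mykkeltveit's decycling set, then its mirror image, then the rest, using
  the complex embedding `P(u) = sum_j u_j exp(2 pi i j / k)`.  The published
  description does not pin down the sector convention, and the choice is
  *not* cosmetic: anchoring the sector at the positive real axis by
  argument gave measurably different density than Mykkeltveit's original
  crossing rule (`Im(P) <= 0` and `Im(P * omega) > 0`).  The crossing rule
  is the one that reproduces the published benchmark density and is the
  convention adopted here; `P = 0` k-mers (e.g. homopolymers) fall in the
  last class.  This scheme is validated through its measured density, as no
  exact reference definition is available.
* `table_scheme()` — an explicit window-to-index lookup table; the carrier
  for ILP solutions, with JSON round-tripping.

Sequences are handled as integer symbols `0..sigma-1`; DNA maps A,C,G,T to
0,1,2,3.  FASTA input offers three out-of-alphabet policies (`reject`,
`strip`, `skip-split`); `skip-split` is the faithful one for density work
since stripping joins symbols that were never adjacent.

# The ILP search

For forward schemes the program has one integer `x_W in [w]` per window
(vertex of `B_{w+k-1}`) and one binary `y_e` per context (edge).
Forwardness is `x_u <= x_v + 1`; two big-M rows with `M = w` (the tightest
constant the variable ranges admit) force `y_e = 1` unless `x_u = x_v + 1`;
the objective minimizes the number of charged contexts.  For every pure
cycle of `B_{w+k}` the valid cut `sum y >= ceiling(|c|/w)` restates the
necklace bound; the cuts never change the optimum (asserted on small
instances) but prune the search.  Every solution is re-verified: the
returned table is independently checked to be forward and its charged
contexts re-counted by enumeration before anything is reported.

For local schemes the window choice is one-hot encoded (`b[W, a]`,
`sum_a b[W, a] = 1`) and, for each context `C` and offset `a`, the row
`y_C >= b[last, a] - sum_i b[W_i, a + w-1-i]` pins `y_C` to the charged
indicator without any big-M constant.  An integer-x big-M formulation was
tried first and was far outside desk-scale solve times.  Because the charged
set of *any* local scheme is a UHS, pure-cycle cuts and walk covers (every
`w` consecutive contexts contain a charged one) are valid and are added by
default; they are what makes the relaxation informative.  The `y` variables
are left continuous — integral one-hots force them to 0/1 — halving the
integer variable count.

Even so, certifying local optimality is genuinely hard for an open-source
solver on one CPU: at `(sigma=2, w=4, k=2)` the dual bound closes only
slowly.  `solve_local()` therefore runs a deterministic, seeded
simulated-annealing stage first — started from the forward-ILP optimum,
whose local charged count is a valid incumbent — and then asks the ILP to
certify the incumbent by proving one-fewer-charged-context infeasible
within the time limit.  Certification success yields status `"optimal"`;
otherwise the incumbent is returned with status `"feasible"` and the
solver's dual bound, never relabelled.  The solver backend is HiGHS through
SciPy, run as a subprocess behind a solver-agnostic sparse-triplet model
layer; the optimal objective is solver-independent, while the particular
table may differ, which is why only re-verified densities are reported.

# Numerical and scale choices

* Enumeration budgets default to `1e7` contexts (`1e6` for ILP models);
  beyond them functions refuse with an explanatory error rather than
  silently degrade.  `is_forward()` falls back to a seeded sampled check
  with a warning.
* Empirical density divides distinct selected positions by the number of
  k-mer positions `L - k + 1` (not windows); the difference is `O(w/L)` and
  immaterial at the lengths used.
* Random test sequences are i.i.d. uniform, generated from an explicit seed
  with the caller's RNG state restored.  Densities are measured on
  `10^7`-character sequences (matching the published benchmark protocol) in
  the acceptance path and shorter ones in unit tests; at `10^7` positions
  the sampling standard error is about `1e-4`, well inside the
  3-decimal reporting precision.
* Uniform random sequences emulate the null model under which density is
  *defined*.  Real genomes have repeats, skewed composition and long
  homopolymers, which shift measured proportions of sampled k-mers somewhat;
  agreement on random sequences validates the schemes and the theory, not
  genome-specific behaviour.

# Limitations

* The ILP search is for small parameter sets (`sigma^(w+k)` up to the model
  budget); it is a verification instrument, not a scheme factory for
  practical `(w, k)`.
* Local-scheme optima above trivial sizes are reported as certified optima
  only when the solver proves them; otherwise as incumbents, with the dual
  bound attached.
* Canonical (strand-aware) minimizers, syncmer-type schemes without a
  window guarantee, and sequence-specific schemes are out of scope.
* The double-decycling ordering is a reconstruction validated by measured
  density, as discussed above.
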