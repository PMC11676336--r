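# minidens

Density analysis and optimal design of k-mer sampling schemes with a window
guarantee (minimizer schemes and their relatives), for people building or
studying sketching methods in sequence analysis.

A *(w, k)-local scheme* maps every window of `w` consecutive k-mers
(`w + k - 1` symbols) to the index of a sampled k-mer; *forward* schemes
additionally never move the sampled position backwards. Their *density* —
the expected proportion of sampled positions on uniform random input —
equals the fraction of *charged contexts*: strings of length `w + k`
(forward) or `2w + k - 2` (local) whose last window samples a new position.
The package provides:

* **Exact and empirical density.** Charged-context enumeration
  (`exact_density`, `charged_contexts_forward/local`, `is_forward`,
  `verify_uhs`) and fast application of schemes to sequences
  (`select_positions`, `empirical_density`; compiled splitmix64-hash core).
* **Lower bounds on achievable density.** The aperiodic-necklace bound and
  its improvement, in exact big-integer rational arithmetic:

      g_sigma(w,k)  = sum_{p | w+k} M_sigma(p) ceil(p/w) / sigma^(w+k)
      g'_sigma(w,k) = max( g_sigma(w,k), g_sigma(w,k') ),  k' = min {k'' >= k : k'' = 1 (mod w)}

  with `M_sigma(p) = (1/p) sum_{d|p} mu(p/d) sigma^d` the aperiodic necklace
  count (`lower_bound_g`, `lower_bound_g_prime`, `uhs_lower_bound`,
  `local_scheme_bound`, plus the simple form `ceil((w+k)/w)/(w+k)`).
* **Reference schemes.** Random, lexicographic, mod-minimizer, miniception
  and the double-decycling minimizer (Mykkeltveit-embedding classes), all
  seed-reproducible, plus explicit `table_scheme`s with JSON round-trip.
* **Optimal scheme search.** An ILP over De Bruijn graph windows with
  pure-cycle cuts (`solve_forward`), and a local-scheme search coupling a
  seeded annealing primal stage with ILP certification (`solve_local`).
  Every reported solution is re-verified by independent enumeration.
* **Combinatorial machinery.** Necklace/aperiodic-necklace counts, Euler's
  totient, the Moebius function, pure-cycle enumeration and canonical
  rotations, exact at any size via a built-in big-integer layer.

## Worked example

```r
library(minidens)

# how sparse can any forward scheme be at minimap2's HiFi defaults?
lower_bound_g_prime(4, 19, 19)
#> <bound_result g_prime> sigma=4 w=19 k=19 (k' = 20)
#>   23248573454127484128984 / 302231454903657293676544 = 0.077

# exact density of a tiny scheme by charged-context enumeration
exact_density(lexicographic_minimizer(2, 1, 2), "forward")
#> <density_estimate exact> 0.750000 (= 6/8) over 8 contexts

# a random minimizer measured on one million random DNA characters
seq4 <- random_sequence(4, 1e6, seed = 1)
empirical_density(random_minimizer(5, 31, 4, seed = 2), seq4)
#> <density_estimate empirical> 0.333529 over 999970 k-mer positions

# search for a provably optimal forward scheme; 6/8 meets the bound above
solve_forward(2, 2, 1)
#> <ilp_solution forward> sigma=2 w=2 k=1: status=optimal, 6 charged contexts, density 6/8 = 0.750000
```

The first call says no (19,19)-forward scheme can sample fewer than 7.7% of
positions; the measured 0.333 for the random minimizer matches its expected
`2/(w+1)`; and at `(w=2, k=1)` the ILP optimum coincides with the bound —
the bound is tight there.

A thin command-line front end over the same functions ships in
`inst/cli/minidens.R` (subcommands `bound`, `necklaces`, `density`,
`sample`, `optimize`, `table1`), e.g.

```sh
Rscript inst/cli/minidens.R bound --sigma 4 --w 19 --k 19 --kind gprime
```

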