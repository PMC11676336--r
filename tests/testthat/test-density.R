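test_that("exact density reproduces hand-enumerated charged contexts", {
  lex <- lexicographic_minimizer(2, 1, 2)
  cs <- charged_contexts_forward(lex)
  expect_identical(length(cs$members), 6L)
  expect_identical(cs$n_total, 8)
  expect_equal(exact_density(lex, "forward")$value, 0.75)
  # equals the necklace bound: this scheme is optimal at (2,1)
  expect_equal(exact_density(lex, "forward")$value, lower_bound_g(2, 2, 1)$value)

  s0 <- table_scheme(2, 2, 2, rep(0L, 8))
  expect_identical(length(charged_contexts_forward(s0)$members), 16L)
  expect_identical(length(charged_contexts_local(s0)$members), 16L)
})

test_that("local-mode density equals forward-mode density for forward schemes", {
  for (s in builtin_schemes(2, 2, 2)) {
    expect_equal(exact_density(s, "local")$value,
                 exact_density(s, "forward")$value,
                 info = s$name)
  }
  lex <- lexicographic_minimizer(2, 1, 2)
  expect_equal(exact_density(lex, "local")$value, 0.75)
})

test_that("w = 1 schemes have density one in both modes", {
  s <- random_minimizer(1, 2, 2)
  expect_identical(exact_density(s, "forward")$value, 1)
  expect_identical(exact_density(s, "local")$value, 1)
})

test_that("exact density agrees with the cycle-walk oracle", {
  for (par in list(c(2, 2), c(3, 2))) {
    for (s in builtin_schemes(par[1], par[2], 2)) {
      expect_equal(exact_density(s, "forward")$charged,
                   oracle_cycle_walk_charged(s),
                   info = sprintf("%s (%d,%d)", s$name, par[1], par[2]))
    }
  }
})

test_that("exact density agrees with the sliding-window simulation oracle", {
  n <- 20000
  for (s in list(lexicographic_minimizer(2, 1, 2),
                 random_minimizer(3, 2, 2, seed = 4),
                 mod_minimizer(2, 3, 2, seed = 4))) {
    d <- exact_density(s, "forward")$value
    seq <- random_sequence(2, n, seed = 21)
    sim <- oracle_sliding_density(s, seq)
    tol <- 3 * sqrt(d * (1 - d) / n)
    expect_lt(abs(sim - d), tol + 1e-9, )
    emp <- empirical_density(s, seq)$value
    expect_lt(abs(emp - d), tol + 1e-9)
  }
})

test_that("empirical density handles edge cases", {
  lex <- lexicographic_minimizer(2, 1, 2)
  expect_error(empirical_density(lex, "0"), "shorter")
  s0 <- table_scheme(3, 2, 2, rep(0L, 16))
  expect_gt(empirical_density(s0, random_sequence(2, 1000, seed = 2))$value, 0.99)
})

test_that("exact densities dominate the forward-scheme lower bound", {
  for (w in 2:4) {
    for (k in 2:3) {
      gp <- lower_bound_g_prime(2, w, k)$value
      for (s in builtin_schemes(w, k, 2)) {
        expect_gte(exact_density(s, "forward")$value, gp - 1e-12,
                   label = sprintf("%s (%d,%d)", s$name, w, k))
      }
    }
  }
})

test_that("is_forward returns a genuine counterexample for a crafted table", {
  expect_true(is_forward(random_minimizer(3, 2, 2))$forward)
  # windows are 3-mers at (w=3,k=1): map 000 -> 2, 001 -> 0 violates
  # forwardness on context 0001
  tab <- rep(0L, 8)
  tab[digits_to_int(c(0, 0, 0), 2) + 1L] <- 2L
  s <- table_scheme(3, 1, 2, tab)
  chk <- is_forward(s)
  expect_false(chk$forward)
  ctx <- chk$counterexample
  expect_length(ctx, 4)
  a <- s$rule(ctx[1:3]); b <- s$rule(ctx[2:4])
  expect_gt(a, b + 1L)
})

test_that("charged context sets are universal hitting sets", {
  for (par in list(c(2, 2), c(3, 2))) {
    for (s in builtin_schemes(par[1], par[2], 2)) {
      expect_true(verify_uhs(charged_contexts_forward(s), par[1]),
                  info = sprintf("forward %s (%d,%d)", s$name, par[1], par[2]))
      expect_true(verify_uhs(charged_contexts_local(s), par[1]),
                  info = sprintf("local %s (%d,%d)", s$name, par[1], par[2]))
    }
  }
  expect_false(verify_uhs(numeric(0), w = 2, sigma = 2, ell = 3))
  expect_true(verify_uhs(0:7, w = 1, sigma = 2, ell = 3))
})

test_that("enumeration refuses work beyond its budget", {
  s <- random_minimizer(10, 22, 4)
  expect_error(charged_contexts_forward(s), "budget")
  expect_error(exact_density(s, "local"), "budget")
})
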