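test_that("g matches hand-derived exact fractions", {
  g <- lower_bound_g(2, 2, 1)
  expect_identical(as.numeric(g$num), 6)
  expect_identical(as.numeric(g$den), 8)
  expect_equal(g$value, 0.75)

  g <- lower_bound_g(2, 4, 2)
  expect_identical(as.numeric(g$num), 23)
  expect_identical(as.numeric(g$den), 64)

  # w = 1: every position sampled, bound collapses to 1
  for (sigma in c(2, 4)) {
    for (k in c(1, 3, 7)) {
      expect_equal(lower_bound_g(sigma, 1, k)$value, 1)
    }
  }
})

test_that("g' takes the max over k and k' and records k'", {
  gp <- lower_bound_g_prime(2, 4, 2)
  expect_identical(gp$k_prime, 5L)
  expect_identical(as.numeric(gp$num), 23)  # g(4,2)=23/64 beats g(4,5)=172/512
  expect_identical(as.numeric(lower_bound_g(2, 4, 5)$num), 172)

  expect_identical(lower_bound_g_prime(4, 5, 31)$k_prime, 31L)
  expect_identical(lower_bound_g_prime(4, 12, 20)$k_prime, 25L)
  expect_identical(lower_bound_g_prime(4, 19, 19)$k_prime, 20L)

  # published reference values at 3 decimals
  expect_equal(round(lower_bound_g_prime(4, 5, 31)$value, 3), 0.222)
  expect_equal(round(lower_bound_g_prime(4, 12, 20)$value, 3), 0.108)
  expect_equal(round(lower_bound_g_prime(4, 19, 19)$value, 3), 0.077)

  # g' >= g always, equality when k = 1 (mod w)
  for (w in 2:8) {
    for (k in 1:10) {
      g <- lower_bound_g(2, w, k)
      gp <- lower_bound_g_prime(2, w, k)
      expect_gte(gp$value, g$value)
      if ((k - 1) %% w == 0) expect_identical(gp$value, g$value)
    }
  }
})

test_that("simple and prior bounds evaluate correctly and rank as expected", {
  sb <- simple_bound(19, 20)
  expect_identical(as.numeric(sb$num), 3)
  expect_identical(as.numeric(sb$den), 39)
  expect_equal(simple_bound(1, 5)$value, 1)
  for (w in 2:10) expect_equal(simple_bound(w, 1)$value, 2 / (w + 1))

  expect_equal(prior_bound(19, 19), 1.5 / 37.5)
  expect_equal(prior_bound(5, 31), 1.5 / 35.5)
  # the necklace bound beats the prior bound on all published parameter rows
  for (row in list(c(5, 31), c(12, 20), c(19, 19))) {
    expect_lt(prior_bound(row[1], row[2]),
              lower_bound_g_prime(4, row[1], row[2])$value)
  }
})

test_that("theorem chain g >= simple >= 1/w holds, strictly in the middle for w>1", {
  for (sigma in c(2, 4)) {
    for (w in 1:30) {
      for (k in 1:30) {
        g <- lower_bound_g(sigma, w, k)
        sb <- simple_bound(w, k)
        # all comparisons by exact cross-multiplication
        expect_gte(bn_cmp(bn_mul(g$num, sb$den), bn_mul(sb$num, g$den)), 0)
        expect_gte(bn_cmp(bn_mul_small(sb$num, w), sb$den), 0)
        if (w > 1) {
          expect_gt(bn_cmp(bn_mul(g$num, sb$den), bn_mul(sb$num, g$den)), 0)
        }
      }
    }
  }
})

test_that("g is not monotone in k", {
  vals <- vapply(1:12, function(k) lower_bound_g(4, 2, k)$value, numeric(1))
  expect_true(any(diff(vals) > 0))
  expect_gt(lower_bound_g(4, 2, 3)$value, lower_bound_g(4, 2, 2)$value)
})

test_that("UHS lower bound matches the g numerator definitionally", {
  expect_identical(as.numeric(uhs_lower_bound(2, 2, 4)), 9)
  expect_identical(as.numeric(uhs_lower_bound(2, 2, 1)), 2)  # short cycles still count once
  for (sigma in c(2, 4)) {
    for (w in 2:6) {
      for (k in 1:6) {
        expect_true(bn_eq(uhs_lower_bound(sigma, w, w + k),
                          lower_bound_g(sigma, w, k)$num))
      }
    }
  }
  # the large-parameter identity used for sigma^36 * g_4(5,31)
  expect_identical(as.character(uhs_lower_bound(4, 5, 36)),
                   as.character(lower_bound_g(4, 5, 31)$num))
})

test_that("local scheme bound is g' at substituted parameters", {
  lb <- local_scheme_bound(2, 4, 2)
  ref <- lower_bound_g_prime(2, 4, 4)
  expect_identical(lb$value, ref$value)
  expect_identical(local_scheme_bound(2, 2, 2)$value, lower_bound_g_prime(2, 2, 2)$value)
  # the published local optimum respects it
  expect_gte(95 / 256, lb$value)
})

test_that("mod-minimizer asymptotic density equals the simple bound when k = 1 mod w", {
  expect_identical(as.numeric(mod_minimizer_asymptotic_density(19, 20)$num), 3)
  m <- mod_minimizer_asymptotic_density(5, 31)
  expect_identical(as.numeric(m$num), 8)
  expect_identical(as.numeric(m$den), 36)
  expect_error(mod_minimizer_asymptotic_density(5, 32), "mod")
  for (w in 1:50) {
    for (k in seq(1, 100, by = w)) {
      if ((k - 1) %% w != 0) next
      expect_identical(mod_minimizer_asymptotic_density(w, k)$value,
                       simple_bound(w, k)$value)
    }
  }
})
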