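test_that("lexicographic minimizer picks the least k-mer, leftmost on ties", {
  lex <- lexicographic_minimizer(2, 1, 2)
  expect_identical(lex$rule(c(1L, 0L)), 1L)
  expect_identical(lex$rule(c(0L, 1L)), 0L)
  expect_identical(lex$rule(c(0L, 0L)), 0L)
  # all-equal k-mers: any scheme must take the leftmost
  for (s in builtin_schemes(3, 2, 2)) {
    expect_identical(s$rule(rep(0L, 4)), 0L)
  }
  expect_error(lex$rule(c(0L, 1L, 0L)), "length")
  expect_error(lex$rule(c(0L, 2L)), "sigma")
})

test_that("select_positions matches a hand-traced run and the window guarantee", {
  lex <- lexicographic_minimizer(2, 1, 2)
  # windows of "0101": "01"->0, "10"->1, "01"->0  => positions 0, 2, 2
  expect_identical(select_positions(lex, "0101"), c(0L, 2L))
  expect_identical(select_positions(lex, c(0L, 1L, 0L, 1L)), c(0L, 2L))
  expect_warning(p <- select_positions(lex, "0"), "shorter")
  expect_identical(p, integer(0))

  for (sigma in c(2, 4)) {
    seq <- random_sequence(sigma, 3000, seed = 99)
    for (w in c(3, 5)) {
      for (k in c(2, 4)) {
        for (s in builtin_schemes(w, k, sigma)) {
          pos <- select_positions(s, seq)
          expect_true(all(diff(pos) <= w),
                      info = sprintf("%s (%d,%d,%d)", s$name, w, k, sigma))
          expect_true(all(diff(pos) >= 1))
          expect_lte(max(pos), length(seq) - k)
        }
      }
    }
  }
})

test_that("hash order and selections are seed-stable and seed-sensitive", {
  expect_identical(hash_order_hex(c(0, 1, 2, 3), 1), hash_order_hex(c(0, 1, 2, 3), 1))
  expect_false(hash_order_hex(c(0, 1, 2, 3), 1) == hash_order_hex(c(0, 1, 2, 3), 2))
  seq <- random_sequence(4, 5000, seed = 7)
  a <- select_positions(random_minimizer(5, 8, 4, seed = 10), seq)
  b <- select_positions(random_minimizer(5, 8, 4, seed = 10), seq)
  c <- select_positions(random_minimizer(5, 8, 4, seed = 11), seq)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("mod-minimizer and miniception choose their t parameter as documented", {
  expect_identical(mod_minimizer(5, 31, 4)$params$t, 6L)
  expect_identical(mod_minimizer(12, 20, 4)$params$t, 8L)
  expect_identical(mod_minimizer(5, 2, 4)$params$t, 2L)  # capped at k
  expect_identical(mod_minimizer(5, 11, 256, t = 1)$params$t, 1L)
  expect_identical(miniception(19, 19, 4)$params$t, 4L)
  expect_identical(miniception(5, 31, 4)$params$t, 26L)
  expect_error(miniception(4, 3, 4, t = 5), "t must")
})

test_that("every built-in scheme is forward on exhaustively checkable sizes", {
  for (w in 2:4) {
    for (k in 2:4) {
      for (s in builtin_schemes(w, k, 2)) {
        chk <- is_forward(s)
        expect_true(chk$forward, info = sprintf("%s (%d,%d)", s$name, w, k))
      }
    }
  }
  for (s in builtin_schemes(3, 2, 4)) {
    expect_true(is_forward(s)$forward, info = paste(s$name, "sigma=4"))
  }
})

test_that("table schemes validate, evaluate and round-trip through JSON", {
  expect_error(table_scheme(2, 2, 2, c(0, 1)), "entries")
  expect_error(table_scheme(2, 2, 2, rep(5, 8)), "\\[w\\]")
  tab <- c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L)
  s <- table_scheme(2, 2, 2, tab)
  expect_identical(s$rule(c(0L, 1L, 0L)), tab[digits_to_int(c(0, 1, 0), 2) + 1L])
  path <- tempfile(fileext = ".json")
  s2 <- read_scheme(write_scheme(s, path))
  for (e in 0:7) {
    win <- int_to_digits(e, 3, 2)
    expect_identical(s2$rule(win), s$rule(win))
  }
  # hash schemes reconstruct by name and parameters
  m <- mod_minimizer(4, 6, 4, seed = 9)
  m2 <- read_scheme(write_scheme(m, tempfile(fileext = ".json")))
  seq <- random_sequence(4, 500, seed = 1)
  expect_identical(select_positions(m, seq), select_positions(m2, seq))
})

test_that("constant-zero table scheme selects every window start", {
  s <- table_scheme(3, 2, 2, rep(0L, 16))
  seq <- random_sequence(2, 200, seed = 5)
  expect_identical(select_positions(s, seq), 0:(200 - 4))
  expect_identical(exact_density(s, "forward")$value, 1)
})

test_that("lifting a scheme to larger k by ignoring trailing symbols preserves density", {
  base <- random_minimizer(2, 2, 2, seed = 3)
  d_base <- exact_density(base, "forward")
  for (k2 in 3:4) {
    span2 <- 2 + k2 - 1
    tab <- vapply(0:(2^span2 - 1), function(e) {
      win <- int_to_digits(e, span2, 2)
      base$rule(win[1:3])
    }, integer(1))
    lifted <- table_scheme(2, k2, 2, tab)
    expect_identical(exact_density(lifted, "forward")$value, d_base$value)
  }
})

test_that("sequence encoding maps DNA and digit strings and rejects others", {
  expect_identical(encode_sequence("ACGT", 4), 0:3)
  expect_identical(encode_sequence("acgt", 4), 0:3)
  expect_identical(encode_sequence("0121", 3), c(0L, 1L, 2L, 1L))
  expect_error(encode_sequence("ACGN", 4), "alphabet")
  expect_error(encode_sequence(c(0L, 4L), 4), "sigma")
})
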