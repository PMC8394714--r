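test_that("d = 3 symbols follow the documented pattern enumeration", {
  # one window per pattern, built from its defining inequality chain
  windows <- list(
    c(1, 2, 3),  # x1 <= x2 <= x3 -> 1
    c(1, 3, 2),  # x1 <= x3 <= x2 -> 2
    c(2, 1, 3),  # x2 <= x1 <= x3 -> 3
    c(2, 3, 1),  # x3 <= x1 <= x2 -> 4
    c(3, 1, 2),  # x2 <= x3 <= x1 -> 5
    c(3, 2, 1))  # x3 <= x2 <= x1 -> 6
  for (i in seq_along(windows))
    expect_identical(ordinal_symbols(windows[[i]], 3), i)
})

test_that("symbol extraction matches hand-worked examples and length law", {
  expect_identical(ordinal_symbols(c(1, 2, 3, 4, 5), 3), c(1L, 1L, 1L))
  expect_identical(ordinal_symbols(c(0.1, 0.5, 0.9, 0.2), 3), c(1L, 4L))
  set.seed(11)
  for (d in 2:5) {
    for (n in c(d, d + 1, 37)) {
      s <- ordinal_symbols(stats::rnorm(n), d)
      expect_length(s, n - d + 1)
      expect_true(all(s >= 1 & s <= factorial(d)))
    }
  }
})

test_that("ties resolve by the stable earliest-index-wins rule", {
  expect_identical(ordinal_symbols(c(1, 1, 2), 3), 1L)  # x1 <= x2 <= x3
  expect_identical(ordinal_symbols(c(2, 1, 1), 3), 5L)  # x2 <= x3 <= x1
  expect_identical(ordinal_symbols(c(1, 1, 1), 3), 1L)
})

test_that("invalid symbolization inputs are rejected", {
  expect_error(ordinal_symbols(c(1, 2), 3), "shorter")
  expect_error(ordinal_symbols(c(1, NA, 2, 3), 3), "non-finite")
  expect_error(ordinal_symbols(c(1, Inf, 2, 3), 3), "non-finite")
  expect_error(ordinal_symbols(1:10, 1), "between 2 and 7")
  expect_error(ordinal_symbols(1:10, 8), "between 2 and 7")
})

test_that("pattern distributions count correctly", {
  d1 <- pattern_distribution(c(1L, 1L, 1L), 6)
  expect_equal(d1$p, 1)
  expect_equal(d1$codes, 1L)
  d2 <- pattern_distribution(1:6, 6)
  expect_equal(d2$p, rep(1 / 6, 6))
  d3 <- pattern_distribution(c(1L, 4L), 6)
  expect_equal(d3$p, c(0.5, 0.5))
  expect_error(pattern_distribution(integer(0), 6), "empty")
  expect_error(pattern_distribution(1:7, 6), "alphabet_size")
  expect_equal(sum(pattern_distribution(sample(1:6, 100, TRUE), 6)$p), 1,
               tolerance = 1e-12)
})

test_that("composite encoding matches the positional formula and is injective", {
  expect_equal(combine_channel_symbols(rbind(1L, 1L), d = 3), 7)
  expect_equal(combine_channel_symbols(rbind(6L, 6L), d = 3), 42)
  # m = 1 degenerates to the symbol itself
  s <- sample(1:6, 20, TRUE)
  expect_equal(combine_channel_symbols(matrix(s, 1), d = 3), as.numeric(s))
  # exhaustive injectivity for d <= 4, m <= 3
  for (d in 2:4) {
    for (m in 1:3) {
      fd <- factorial(d)
      tuples <- as.matrix(expand.grid(rep(list(seq_len(fd)), m)))
      codes <- combine_channel_symbols(t(tuples), d = d)
      expect_equal(length(unique(codes)), fd^m)
    }
  }
  expect_error(combine_channel_symbols(rbind(1L, 7L), d = 3), "out of range")
  expect_error(combine_channel_symbols(list(1:3, 1:4), d = 3), "mismatched")
  # alphabet must stay exactly representable
  big <- matrix(1L, 5, 10)
  expect_error(combine_channel_symbols(big, d = 7), "exceeds")
})

test_that("permutation entropy obeys its limit laws", {
  # single-pattern law: strictly monotone series
  for (d in 2:5) {
    expect_identical(permutation_entropy(seq_len(50), d)$value, 0)
    expect_identical(permutation_entropy(-seq_len(50), d)$value, 0)
  }
  # i.i.d. noise approaches the uniform maximum
  set.seed(101)
  pe <- permutation_entropy(stats::runif(10000), 3)
  expect_lt(abs(pe$value - 1), 0.01)
  expect_true(pe$value <= 1 && pe$value >= 0)
})

test_that("entropy values are invariant under strictly monotone channel maps", {
  set.seed(21)
  x <- stats::rnorm(300)
  X <- rbind(x, stats::rnorm(300))
  for (f in list(function(v) 2 * v + 1, exp, atan)) {
    expect_identical(ordinal_symbols(f(x), 4), ordinal_symbols(x, 4))
    expect_identical(mmpe(rbind(f(X[1, ]), f(X[2, ])), 3)$value,
                     mmpe(X, 3)$value)
  }
})

test_that("MMPE reduces to PE for m = 1 and PE/m for stacked copies", {
  set.seed(31)
  x <- stats::rnorm(500)
  pe <- permutation_entropy(x, 3)
  m1 <- mmpe(matrix(x, 1), 3)
  expect_identical(m1$value, pe$value)
  m2 <- mmpe(rbind(x, x), 3)
  expect_equal(m2$value, pe$value / 2, tolerance = 1e-14)
  m3 <- mmpe(rbind(x, x, x), 3)
  expect_equal(m3$value, pe$value / 3, tolerance = 1e-14)
})

test_that("MMPE of independent channels approaches 1", {
  X <- synth_series("iid_uniform", m = 2, n = 50000, seed = 7)
  expect_lt(abs(mmpe(X, 3)$value - 1), 0.02)
})

test_that("MPE behaves per its cross-channel definition", {
  # fixed strict channel ordering at every instant -> single pattern
  x <- stats::rnorm(100)
  expect_identical(mpe(rbind(x, x + 10))$value, 0)
  # alternating 2 x 4 hand case: both patterns equally likely
  expect_equal(mpe(rbind(c(0, 1, 0, 1), c(1, 0, 1, 0)))$value, 1)
  # independent channels approach the uniform maximum over m! patterns
  set.seed(41)
  X <- matrix(stats::runif(3 * 50000), 3)
  expect_lt(abs(mpe(X)$value - 1), 0.02)
  # the channel count is the embedding dimension
  expect_equal(mpe(matrix(stats::runif(4 * 100), 4))$d, 4)
  expect_error(mpe(matrix(1:10, 1)), "at least 2 channels")
})

test_that("estimators match the naive dictionary-counting oracle", {
  set.seed(51)
  for (i in 1:40) {
    n <- sample(10:30, 1)
    d <- sample(2:4, 1)
    m <- sample(1:3, 1)
    X <- matrix(stats::rnorm(m * n), m)
    expect_equal(mmpe(X, d)$value, oracle_entropy(X, d, "MMPE"),
                 tolerance = 1e-12)
    expect_equal(permutation_entropy(X[1, ], d)$value,
                 oracle_entropy(X[1, ], d, "PE"), tolerance = 1e-12)
    if (m >= 2)
      expect_equal(mpe(X)$value, oracle_entropy(X, estimator = "MPE"),
                   tolerance = 1e-12)
  }
})
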