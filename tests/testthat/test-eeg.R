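test_that("window planning reproduces the 1-based sliding scheme", {
  p <- plan_windows(10500, length = 10000, step = 500)
  expect_equal(p$start, c(1L, 501L))
  expect_equal(p$end, c(10000L, 10500L))
  expect_equal(nrow(plan_windows(10000, length = 10000)), 1L)
  # 31,000 samples: formula gives 43 windows, capped at the study's 40
  expect_equal(nrow(plan_windows(31000)), 40L)
  expect_equal(nrow(plan_windows(31000, max_windows = Inf)), 43L)
  expect_error(plan_windows(9000, length = 10000), "shorter")
})

test_that("one-way ANOVA matches hand computation and conserves SS/df", {
  a <- anova_oneway(c(1, 2, 3), c(2, 3, 4))
  expect_equal(a$ss_columns, 1.5)
  expect_equal(a$ss_error, 4)
  expect_equal(a$F, 1.5)
  # 36 + 36 means give the Columns 1 / Error 70 / Total 71 layout
  set.seed(61)
  a36 <- anova_oneway(stats::rnorm(36), stats::rnorm(36))
  expect_equal(unname(a36$df), c(1L, 70L, 71L))
  # identical groups: no between-group variance
  g <- c(1, 2, 3, 4)
  a0 <- anova_oneway(g, g)
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)
  expect_error(anova_oneway(c(2, 2), c(2, 2)), "identical")
  expect_error(anova_oneway(1, c(1, 2)), "at least 2")
})

test_that("two-group F equals t squared and agrees with aov", {
  set.seed(62)
  for (i in 1:100) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    g1 <- stats::rnorm(n1); g2 <- stats::rnorm(n2, mean = 0.5)
    a <- anova_oneway(g1, g2)
    tt <- stats::t.test(g1, g2, var.equal = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(a$ss_columns + a$ss_error, a$ss_total, tolerance = 1e-9)
    expect_equal(sum(a$df[1:2]), unname(a$df[3]))
  }
  # cross-check the full table against stats::aov once
  g1 <- stats::rnorm(10); g2 <- stats::rnorm(12, 1)
  a <- anova_oneway(g1, g2)
  ref <- summary(stats::aov(c(g1, g2) ~ rep(c("b", "d"), c(10, 12))))[[1]]
  expect_equal(a$ss_columns, ref$`Sum Sq`[1], tolerance = 1e-10)
  expect_equal(a$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(a$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("normality screen is calibrated and has power", {
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    normality_screen(stats::rnorm(1000))$p_value > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  set.seed(63)
  expect_lt(normality_screen(stats::runif(500))$p_value, 0.05)
  expect_error(normality_screen(rep(1, 20)), "constant")
  expect_error(normality_screen(stats::rnorm(5)), "at least 8")
})

test_that("windowed entropy yields bounded values and propagates errors", {
  pair <- synth_series("two_regime_eeg", 21, 12000, seed = 71)
  w <- windowed_entropy(pair$task, estimator = "MMPE", d = 4,
                        m_override = 4, length = 6000, step = 500,
                        max_windows = 8)
  expect_length(w$values, 8)
  expect_true(all(is.finite(w$values) & w$values >= 0 & w$values <= 1))
  expect_equal(w$mean, mean(w$values))
  # per-window preprocessing surfaces the failing window index
  X <- rbind(c(rep(1, 50), stats::rnorm(50)), stats::rnorm(100))
  expect_error(
    windowed_entropy(X, estimator = "MMPE", d = 3, use_pca = FALSE,
                     scope = "window", length = 50, step = 50,
                     max_windows = 5),
    "window 1")
})

test_that("record-scope window slicing equals per-window evaluation", {
  set.seed(72)
  X <- matrix(stats::rnorm(2 * 3000), 2)
  args <- list(estimator = "MMPE", d = 4, use_pca = FALSE,
               length = 1000, step = 500, max_windows = 5)
  rec <- do.call(windowed_entropy, c(list(X), args, scope = "record"))
  win <- do.call(windowed_entropy, c(list(X), args, scope = "window"))
  expect_equal(rec$values, win$values, tolerance = 1e-12)
  # MPE is not invariant to per-channel rescaling, so the two scopes give
  # close but not identical values (different normalization constants)
  X3 <- rbind(X, stats::rnorm(3000))
  mp_rec <- windowed_entropy(X3, estimator = "MPE", use_pca = FALSE,
                             length = 1000, step = 500, scope = "record")
  mp_win <- windowed_entropy(X3, estimator = "MPE", use_pca = FALSE,
                             length = 1000, step = 500, scope = "window")
  expect_equal(mp_rec$values, mp_win$values, tolerance = 0.1)
})

test_that("MPE on 4 reduced components uses the 4! cross-channel alphabet", {
  E <- synth_series("common_source", m = 21, n = 3000, seed = 73)
  P <- preprocess_chain(E, m_override = 4)
  r <- mpe(P)
  expect_equal(r$d, 4)
  expect_equal(r$distribution$alphabet_size, 24)
})

test_that("the two-state study separates the regimes on synthetic subjects", {
  records <- make_small_study(seed = 81)
  st <- run_two_state_study(records, d = 4, m_override = 4,
                            length = small_plan$length,
                            step = small_plan$step,
                            max_windows = small_plan$max_windows)
  expect_lt(st$anova$p, 0.05)
  expect_gt(mean(st$subject_means$during), mean(st$subject_means$before))
  expect_equal(st$anova$ss_columns + st$anova$ss_error, st$anova$ss_total,
               tolerance = 1e-9)
  expect_equal(dim(st$window_values$before), c(8L, 8L))
  lf <- study_long_format(st)
  expect_named(lf, c("subject", "state", "window", "value"))
  expect_equal(nrow(lf), 2 * 8 * 8)
})

test_that("larger d sharpens the separation (median over seeds)", {
  ps <- vapply(c(82, 83, 84), function(seed) {
    records <- make_small_study(seed)
    vapply(c(3, 5), function(dd)
      run_two_state_study(records, d = dd, m_override = 4,
                          length = small_plan$length,
                          step = small_plan$step,
                          max_windows = small_plan$max_windows)$anova$p,
      numeric(1))
  }, numeric(2))
  expect_lte(stats::median(ps[2, ]), stats::median(ps[1, ]))
})

test_that("random channel draws fail more often than the PCA pipeline", {
  records <- make_small_study(seed = 85)
  pca_p <- run_two_state_study(records, d = 4, m_override = 4,
                               length = small_plan$length,
                               step = small_plan$step,
                               max_windows = small_plan$max_windows)$anova$p
  rce <- random_channel_experiment(records, n_channels = 4, repeats = 6,
                                   seed = 86, d = 4,
                                   length = small_plan$length,
                                   step = small_plan$step,
                                   max_windows = small_plan$max_windows)
  expect_length(rce$p_values, 6)
  expect_gt(rce$frac_above_05, mean(pca_p > 0.05))
  # reproducible channel draws
  rce2 <- random_channel_experiment(records, n_channels = 4, repeats = 2,
                                    seed = 86, d = 4,
                                    length = small_plan$length,
                                    step = small_plan$step,
                                    max_windows = small_plan$max_windows)
  expect_identical(rce$channels[1:2, ], rce2$channels)
})
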