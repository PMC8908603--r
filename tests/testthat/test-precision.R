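test_that("within-subject CoV follows the root-mean-squared formula", {
  # identical pairs: a deterministic method has exactly zero CoV
  p0 <- paired_measurements(c(100, 98, 105), c(100, 98, 105))
  cv0 <- cov_within_subject(p0)
  expect_identical(cv0$cov_pct, 0)
  expect_identical(cv0$sem, 0)

  # hand-computed example: d = (-2, 0, 4)
  p1 <- paired_measurements(c(100, 98, 105), c(102, 98, 101))
  cv1 <- cov_within_subject(p1)
  expect_equal(cv1$sem, sqrt(20 / 6), tolerance = 1e-12)
  expect_equal(cv1$cov_pct, 100 * sqrt(20 / 6) / (604 / 6), tolerance = 1e-12)
  expect_equal(round(cv1$sem, 4), 1.8257)
  expect_equal(round(cv1$cov_pct, 4), 1.8137)

  # scale equivariance
  k <- 3.7
  cvk <- cov_within_subject(paired_measurements(k * p1$x1, k * p1$x2))
  expect_equal(cvk$cov_pct, cv1$cov_pct, tolerance = 1e-12)
  expect_equal(cvk$sem, k * cv1$sem, tolerance = 1e-12)

  expect_error(cov_within_subject(paired_measurements(c(1, -1), c(-1, 1))),
               class = "data_error")
})

test_that("CoV equals the subject-factor ANOVA within-subject SD", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    m <- rnorm(n, 100, 12)
    x1 <- m + rnorm(n, 0, 4)
    x2 <- m + rnorm(n, 0, 4)
    sem <- cov_within_subject(paired_measurements(x1, x2))$sem
    expect_equal(sem, anova_sem_oracle(x1, x2), tolerance = 1e-9)
  }
})

test_that("statistics are invariant to subject permutation", {
  set.seed(12)
  x1 <- rnorm(20, 100, 10)
  x2 <- x1 + rnorm(20, 0, 3)
  ord <- sample(20)
  a <- cov_within_subject(paired_measurements(x1, x2))
  b <- cov_within_subject(paired_measurements(x1[ord], x2[ord]))
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(ccc(x1, x2), ccc(x1[ord], x2[ord]), tolerance = 1e-12)
  ba1 <- bland_altman(x1, x2)
  ba2 <- bland_altman(x1[ord], x2[ord])
  expect_equal(ba1, ba2, tolerance = 1e-12)
})

test_that("bootstrap CIs are seeded, degenerate-safe and sensible", {
  p <- paired_measurements(rep(100, 10), rep(100, 10) + rep(2, 10))
  stat <- function(q) mean(q$x1 - q$x2)
  ci <- bootstrap_ci(p, stat, n_boot = 200, seed = 4)
  expect_equal(ci$ci_low, ci$estimate)
  expect_equal(ci$ci_high, ci$estimate)

  set.seed(77)
  x1 <- rnorm(30, 100, 10)
  x2 <- x1 + rnorm(30, 0, 3)
  pm <- paired_measurements(x1, x2)
  covstat <- function(q) cov_within_subject(q)$cov_pct
  c1 <- bootstrap_ci(pm, covstat, n_boot = 500, seed = 9)
  c2 <- bootstrap_ci(pm, covstat, n_boot = 500, seed = 9)
  expect_identical(c1, c2)
  expect_lte(c1$ci_low, c1$estimate)
  expect_gte(c1$ci_high, c1$estimate)
  c3 <- bootstrap_ci(pm, covstat, n_boot = 500, seed = 10, type = "bca")
  expect_lt(c3$ci_low, c3$ci_high)
})

test_that("Lin's CCC matches its closed forms and a direct oracle", {
  set.seed(5)
  x <- rnorm(40, 50, 8)
  expect_equal(ccc(x, x), 1.0, tolerance = 1e-12)

  cshift <- 4
  v <- mean((x - mean(x))^2)
  expect_equal(ccc(x, x + cshift), 2 * v / (2 * v + cshift^2),
               tolerance = 1e-12)
  expect_lt(ccc(x, x + cshift), 1)

  y <- 0.8 * x + rnorm(40, 0, 5)
  mx <- mean(x); my <- mean(y)
  oracle <- 2 * mean((x - mx) * (y - my)) /
    (mean((x - mx)^2) + mean((y - my)^2) + (mx - my)^2)
  expect_equal(ccc(x, y), oracle, tolerance = 1e-12)
  expect_error(ccc(x, rep(1, 40)), class = "data_error")
})

test_that("Bland-Altman bias and limits match direct computation", {
  set.seed(6)
  x <- rnorm(25, 120, 15)
  expect_equal(bland_altman(x, x), list(bias = 0, loa_low = 0, loa_high = 0))
  ba <- bland_altman(x, x - 3)
  expect_equal(ba$bias, 3, tolerance = 1e-12)
  expect_equal(ba$loa_low, 3, tolerance = 1e-9)
  expect_equal(ba$loa_high, 3, tolerance = 1e-9)

  y <- x + rnorm(25, 1, 2)
  ba2 <- bland_altman(x, y)
  d <- x - y
  expect_equal(ba2$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba2$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba2$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
})

test_that("minimal detectable change is 1.96 sqrt(2) SEM", {
  expect_equal(minimal_detectable_change(0), 0)
  expect_equal(minimal_detectable_change(1), 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(round(minimal_detectable_change(1), 5), 2.77186)
  expect_error(minimal_detectable_change(-1), class = "domain_error")
})

test_that("sample size per group matches quantile arithmetic and power", {
  expect_equal(sample_size_per_group(1), 22L)
  # numerical power-integration oracle
  for (delta in c(0.3, 0.5, 1, 2)) {
    expect_equal(sample_size_per_group(delta), power_n_oracle(delta))
  }
  # monotone decreasing, inverse-square law, and the large-effect limit
  expect_equal(sample_size_per_group(100), 1L)
  n1 <- sample_size_per_group(0.2)
  n2 <- sample_size_per_group(0.1)
  expect_gt(n2 / n1, 3.9)
  expect_lt(n2 / n1, 4.1)
  expect_error(sample_size_per_group(0), class = "domain_error")
})

test_that("sample size reduction follows the inverse-variance law", {
  expect_equal(sample_size_reduction(2, 2, effect = 1), 0)
  red <- sample_size_reduction(2, 2 / sqrt(2), effect = 0.1)
  expect_gt(red, 48)
  expect_lt(red, 52)
  # lower sem never increases the required sample size
  ns <- vapply(seq(2, 0.5, by = -0.25), function(s) {
    sample_size_per_group(1 / (sqrt(2) * s))
  }, integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("precision_report bundles consistent statistics", {
  set.seed(21)
  m <- rnorm(20, 100, 12)
  pm <- paired_measurements(m + rnorm(20, 0, 3), m + rnorm(20, 0, 3))
  pr <- precision_report(pm, metric = "edv_ml", n_boot = 300, seed = 2)
  expect_equal(pr$mdc, 1.96 * sqrt(2) * pr$sem, tolerance = 1e-9)
  expect_lte(pr$bland_altman$loa_low, pr$bland_altman$bias)
  expect_gte(pr$bland_altman$loa_high, pr$bland_altman$bias)
  expect_gte(pr$cov_pct, 0)
  expect_lte(pr$cov_ci_low, pr$cov_pct)
  expect_gte(pr$cov_ci_high, pr$cov_pct)
  # internal consistency: mdc recomputed from CoV and the grand mean
  xbar <- mean(c(pm$x1, pm$x2))
  expect_equal(minimal_detectable_change(pr$cov_pct * xbar / 100), pr$mdc,
               tolerance = 1e-9)
})
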