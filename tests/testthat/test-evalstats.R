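test_that("ICC(2,1) matches hand ANOVA and the published bands", {
  p <- paired_measurements(c(1, 2, 3), c(1, 2, 3))
  r <- icc_2_1(p)
  expect_equal(r$icc, 1)
  expect_identical(r$band, "excellent")
  # constant offset of 1: MSR=2, MSC=1.5, MSE=0 -> ICC = 2/3 ("moderate")
  p <- paired_measurements(auto = c(2, 3, 4), manual = c(1, 2, 3))
  r <- icc_2_1(p)
  expect_equal(r$icc, 2 / 3, tolerance = 1e-12)
  expect_identical(r$band, "moderate")
  # independent random series: ICC near zero
  set.seed(10)
  p <- paired_measurements(rnorm(200), rnorm(200))
  expect_lt(abs(icc_2_1(p)$icc), 0.15)
  # degenerate: zero total variance
  r <- icc_2_1(paired_measurements(c(5, 5, 5), c(5, 5, 5)))
  expect_true(r$degenerate)
  expect_equal(r$icc, 1)
})

test_that("ICC equals a two-way ANOVA oracle on random tables", {
  set.seed(77)
  for (rep in 1:10) {
    y1 <- rnorm(5, 10, 3); y2 <- y1 + rnorm(5, 0.5, 1)
    p <- paired_measurements(y2, y1)
    # independent oracle: mean squares from stats::aov on the long table
    long <- data.frame(y = c(y1, y2),
                       target = factor(rep(1:5, 2)),
                       rater = factor(rep(1:2, each = 5)))
    ms <- summary(stats::aov(y ~ target + rater, data = long))[[1]][, "Mean Sq"]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    icc_oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 5)
    expect_equal(icc_2_1(p)$icc, icc_oracle, tolerance = 1e-10)
  }
})

test_that("Bland-Altman bias and limits of agreement", {
  p <- paired_measurements(c(2, 3, 4, 5), c(1, 2, 3, 4))
  ba <- bland_altman(p)
  expect_equal(ba$bias, 1)
  expect_equal(ba$loa_low, 1)
  expect_equal(ba$loa_high, 1)
  # antisymmetry under swapping the two series
  set.seed(3)
  a <- rnorm(50, 40, 5); b <- a + rnorm(50, -1, 2)
  f <- bland_altman(paired_measurements(a, b))
  g <- bland_altman(paired_measurements(b, a))
  expect_equal(f$bias, -g$bias)
  expect_equal(f$loa_low, -g$loa_high)
  expect_equal(f$loa_high, -g$loa_low)
})

test_that("Bland-Altman recovers the published overall-contrast agreement", {
  # differences drawn at the bias/LoA the clinical comparison reported:
  # bias -1.3 mm, LoA -9.8 / 7.2 mm  => sd = (7.2 - (-1.3)) / 1.96
  set.seed(20)
  n <- 1e4
  manual <- rnorm(n, 41, 6)
  d <- rnorm(n, -1.3, (7.2 + 1.3) / 1.96)
  ba <- bland_altman(paired_measurements(manual + d, manual))
  expect_equal(ba$bias, -1.3, tolerance = 0.2)
  expect_equal(ba$loa_low, -9.8, tolerance = 0.2)
  expect_equal(ba$loa_high, 7.2, tolerance = 0.2)
})

test_that("limits of agreement contain ~95% of large normal samples", {
  set.seed(8)
  n <- 1e5
  manual <- rnorm(n, 40, 5)
  auto <- manual + rnorm(n, 0.5, 2)
  ba <- bland_altman(paired_measurements(auto, manual))
  d <- auto - manual
  cover <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_gte(cover, 0.94)
  expect_lte(cover, 0.96)
})

test_that("exact Wilcoxon p equals full sign enumeration", {
  # 6 positive differences: most extreme ordering, p = 2/64
  p <- paired_measurements(c(2, 3, 4, 5, 6, 7) + 0.5, c(2, 3, 4, 5, 6, 7))
  expect_equal(paired_nonparametrics(p)$wilcoxon_p, 2 / 64)
  # brute-force oracle over all 2^n sign assignments, including ties
  enum_p <- function(d) {
    r <- rank(abs(d)); n <- length(d)
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- signs %*% r
    min(1, 2 * min(mean(Ws >= W), mean(Ws <= W)))
  }
  set.seed(5)
  for (rep in 1:8) {
    n <- sample(5:11, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE) +
      round(rnorm(n), 1)
    d <- d[d != 0]
    if (length(d) < 3) next
    p <- paired_measurements(d + 10, rep(10, length(d)))
    expect_equal(paired_nonparametrics(p)$wilcoxon_p, enum_p(d),
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon edge conventions and Spearman behave", {
  # perfectly antisymmetric differences: two-sided p = 1
  p <- paired_measurements(c(11, 9, 12, 8), c(10, 10, 10, 10))
  expect_equal(paired_nonparametrics(p)$wilcoxon_p, 1)
  # all-zero differences: p = 1 with flag
  p <- paired_measurements(c(1, 2, 3), c(1, 2, 3))
  r <- paired_nonparametrics(p)
  expect_true(r$all_zero)
  expect_equal(r$wilcoxon_p, 1)
  # strictly monotone pairs: Spearman rho = 1
  p <- paired_measurements(c(1, 4, 9, 16), c(1, 2, 3, 4))
  expect_equal(paired_nonparametrics(p)$spearman_r, 1)
  # large-sample normal approximation tracks base R
  set.seed(9)
  a <- rnorm(60, 40, 5); b <- a + rnorm(60, 1, 2)
  ours <- paired_nonparametrics(paired_measurements(a, b))$wilcoxon_p
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(ours, ref, tolerance = 0.02)
})

test_that("error summaries use linear-interpolation quartiles", {
  p <- paired_measurements(c(9, 10, 11), c(10, 10, 10))  # d = {-1, 0, 1}
  es <- error_summary(p)
  expect_equal(es$sys_error$median, 0)
  expect_equal(es$abs_error$median, 1)   # |d| = {1, 0, 1}
  # all-positive differences give a positive systematic median
  p <- paired_measurements(c(11, 12, 13), c(10, 10, 10))
  expect_gt(error_summary(p)$sys_error$median, 0)
  # |median(sys)| <= median(abs) always
  set.seed(13)
  for (rep in 1:20) {
    d <- round(rnorm(sample(3:9, 1)), 2)
    p <- paired_measurements(d + 10, rep(10, length(d)))
    es <- error_summary(p)
    expect_lte(abs(es$sys_error$median), es$abs_error$median + 1e-12)
  }
})

test_that("diagnostic metrics reproduce the published dissection CI", {
  # 37 true positives of 42 dissections
  dg <- diagnostic_metrics(tp = 37, fp = 2, tn = 44, fn = 5)
  expect_equal(100 * dg$sensitivity$estimate, 88.1, tolerance = 0.05)
  expect_equal(100 * dg$sensitivity$lower, 74.4, tolerance = 0.05)
  expect_equal(100 * dg$sensitivity$upper, 96.0, tolerance = 0.05)
  expect_equal(100 * dg$specificity$estimate, 95.7, tolerance = 0.05)
  expect_equal(100 * dg$accuracy$estimate, 92.05, tolerance = 0.05)
  # edge conventions
  dg0 <- diagnostic_metrics(tp = 0, fp = 0, tn = 10, fn = 5)
  expect_equal(dg0$sensitivity$lower, 0)
  dgp <- diagnostic_metrics(tp = 10, fp = 0, tn = 10, fn = 0)
  expect_equal(dgp$accuracy$estimate, 1)
  expect_equal(dgp$accuracy$upper, 1)
  # CI contains the point estimate
  set.seed(21)
  for (rep in 1:10) {
    x <- sample(0:20, 1); n <- 20
    dg <- diagnostic_metrics(tp = x, fp = 0, tn = 1, fn = n - x)
    expect_lte(dg$sensitivity$lower, dg$sensitivity$estimate)
    expect_gte(dg$sensitivity$upper, dg$sensitivity$estimate)
  }
})

test_that("Clopper-Pearson intervals achieve nominal coverage", {
  set.seed(31)
  n <- 42; pr <- 0.88; reps <- 1e4
  x <- rbinom(reps, n, pr)
  lo <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
  expect_gte(mean(lo <= pr & pr <= hi), 0.95)
})

test_that("the agreement battery bundles consistently", {
  set.seed(12)
  manual <- rnorm(80, 42, 6)
  auto <- manual + rnorm(80, -0.5, 1.5)
  ag <- agreement_stats(paired_measurements(auto, manual))
  expect_lte(ag$icc, 1)
  expect_lte(ag$loa_low, ag$bias)
  expect_gte(ag$loa_high, ag$bias)
  expect_gt(ag$icc, 0.9)
  expect_identical(ag$icc_band, "excellent")
})
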