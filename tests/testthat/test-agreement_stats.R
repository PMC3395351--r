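test_that("paired CV: zero for identical replicates, hand-checked otherwise", {
  expect_equal(paired_cv(replicate_table(c(5, 7, 9), c(5, 7, 9))), 0)
  # mean |d| = 1, grand mean = 11 -> 100 / (sqrt(2) * 11) = 6.43
  expect_equal(paired_cv_from_summary(11, 1), 100 / (sqrt(2) * 11),
               tolerance = 1e-12)
  expect_equal(round(paired_cv_from_summary(11, 1), 2), 6.43)
  expect_error(paired_cv(replicate_table(c(-5, 1, 1), c(-5, 2, 1))),
               "grand mean")
})

test_that("paired CV is scale invariant", {
  set.seed(31)
  m1 <- runif(12, 5, 15); m2 <- m1 + rnorm(12, 0, 0.5)
  cv1 <- paired_cv(replicate_table(m1, m2))
  cv2 <- paired_cv(replicate_table(7.3 * m1, 7.3 * m2))
  expect_equal(cv1, cv2, tolerance = 1e-12)
})

test_that("paired CV reproduces published reproducibility cells", {
  ref <- read.csv(system.file("extdata", "reference_reproducibility.csv",
                              package = "spectvoi"))
  cv <- paired_cv_from_summary(ref$mean, ref$mean_abs_diff)
  expect_true(all(abs(cv - ref$cv_printed) <= 0.1))
})

test_that("ICC matches the ANOVA sums-of-squares worked example", {
  tab <- replicate_table(c(10, 12, 14, 16), c(11, 13, 15, 17))
  cons <- icc(tab, "two_way_mixed_consistency")
  abs_ <- icc(tab, "two_way_random_absolute")
  # oracle mean squares: MSR = 13.333, MSC = 2, MSE = 0
  expect_equal(cons$msr, 40 / 3, tolerance = 1e-12)
  expect_equal(cons$msc, 2, tolerance = 1e-12)
  expect_equal(cons$mse, 0, tolerance = 1e-12)
  expect_equal(cons$icc, 1.0, tolerance = 1e-9)
  # ICC(2,1) = MSR / (MSR + k (MSC - MSE) / n) = 13.333 / 14.333
  expect_equal(abs_$icc, 0.9302, tolerance = 1e-3)
})

test_that("identical raters give ICC 1 under both models", {
  tab <- replicate_table(c(3, 8, 1, 9, 4), c(3, 8, 1, 9, 4))
  expect_equal(icc(tab, "two_way_mixed_consistency")$icc, 1.0)
  expect_equal(icc(tab, "two_way_random_absolute")$icc, 1.0)
})

test_that("ICC near zero for independent replicates, undefined when degenerate", {
  set.seed(33)
  tab <- replicate_table(rnorm(200), rnorm(200))
  res <- icc(tab)
  expect_lt(abs(res$icc), 0.15)
  expect_true(res$ci[1] <= 0 && res$ci[2] >= res$icc)
  expect_warning(icc(replicate_table(c(2, 2, 2), c(2, 2, 2))), "undefined")
})

test_that("ICC(3,1) ignores a constant rater shift; ICC(2,1) penalizes it", {
  set.seed(34)
  m1 <- rnorm(30, 10, 3)
  m2 <- m1 + rnorm(30, 0, 0.4)
  base_c <- icc(replicate_table(m1, m2), "two_way_mixed_consistency")$icc
  base_a <- icc(replicate_table(m1, m2), "two_way_random_absolute")$icc
  shift_c <- icc(replicate_table(m1, m2 + 5), "two_way_mixed_consistency")$icc
  shift_a <- icc(replicate_table(m1, m2 + 5), "two_way_random_absolute")$icc
  expect_equal(shift_c, base_c, tolerance = 1e-9)
  expect_lt(shift_a, base_a)
})

test_that("one-sample t-test of absolute differences matches hand arithmetic", {
  # |d| = 1,2,3,4 -> t = 2.5 / (sd/sqrt(4)) = 2.5 / 0.6455 = 3.873, df 3
  tab <- replicate_table(c(11, 22, 33, 44), c(10, 20, 30, 40))
  res <- abs_diff_ttest(tab)
  expect_equal(res$t, 3.873, tolerance = 1e-3)
  expect_equal(res$df, 3)
  expect_equal(res$mean_abs_diff, 2.5)
  expect_error(abs_diff_ttest(replicate_table(c(1, 2, 3), c(2, 3, 4))),
               "zero variance")
})

test_that("absolute differences bounded away from zero give p < .001 at scale", {
  set.seed(36)
  m1 <- rnorm(100, 10, 2)
  m2 <- m1 + sample(c(-1, 1), 100, TRUE) * runif(100, 0.5, 1.5)
  expect_lt(abs_diff_ttest(replicate_table(m1, m2))$p_value, 0.001)
})

test_that("correlations: identity, monotone-nonlinear, rank-formula oracle", {
  x <- c(0.4, 1.1, 2.0, 3.2, 4.7)
  expect_equal(correlation(x, x, "pearson")$r, 1.0)
  expect_equal(correlation(x, x, "spearman")$r, 1.0)
  y <- exp(x)
  expect_equal(correlation(x, y, "spearman")$r, 1.0)
  expect_lt(correlation(x, y, "pearson")$r, 1.0)
  # rank-formula oracle: rho = 1 - 6 sum(d^2) / (n (n^2 - 1))
  xr <- 1:5; yr <- c(2, 1, 4, 3, 5)
  d2 <- sum((rank(xr) - rank(yr))^2)
  oracle <- 1 - 6 * d2 / (5 * 24)
  expect_equal(correlation(xr, yr, "spearman")$r, oracle, tolerance = 1e-12)
  expect_error(correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("OLS fit: exact linear, normal-equations oracle, recovery of truth", {
  x <- 1:10
  f <- ols_fit(2 * x + 3, data.frame(x = x))
  expect_equal(f$r_squared, 1.0, tolerance = 1e-12)
  expect_equal(f$coefficients$B[f$coefficients$term == "x"], 2, tolerance = 1e-9)

  # intercept-only model
  f0 <- ols_fit(c(4, 6, 8, 2), data.frame())
  expect_equal(f0$r_squared, 0)

  # brute-force normal equations on random small instances
  set.seed(41)
  for (i in 1:5) {
    n <- 25
    X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    y <- rnorm(n)
    f <- ols_fit(y, X)
    Xd <- cbind(1, as.matrix(X))
    beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
    expect_equal(f$coefficients$B, as.numeric(beta), tolerance = 1e-8)
  }

  # seeded simulation with known slope
  set.seed(42)
  x <- rnorm(1000)
  y <- 2 * x + rnorm(1000)
  f <- ols_fit(y, data.frame(x = x))
  b <- f$coefficients[f$coefficients$term == "x", ]
  expect_lt(abs(b$B - 2), 3 * b$se)

  expect_error(ols_fit(rnorm(10), data.frame(a = 1:10, b = 2 * (1:10))),
               "rank")
})

test_that("stepwise selection keeps true predictors and drops noise", {
  set.seed(43)
  n <- 500
  x_true <- rnorm(n)
  noise <- data.frame(n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  y <- 1.5 * x_true + rnorm(n)
  sel <- stepwise_select(y, cbind(data.frame(x_true = x_true), noise))
  expect_true("x_true" %in% sel$selected)

  # y identical to a candidate: perfect fit
  sel2 <- stepwise_select(x_true, data.frame(x_true = x_true, other = rnorm(n)))
  expect_identical(sel2$selected, "x_true")
  expect_equal(sel2$model$r_squared, 1.0, tolerance = 1e-12)
})

test_that("stepwise selection on pure noise is usually empty", {
  set.seed(44)
  empty <- 0L
  for (i in 1:20) {
    n <- 200
    y <- rnorm(n)
    cand <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    sel <- stepwise_select(y, cand)
    if (length(sel$selected) == 0) empty <- empty + 1L
  }
  # expected empty share ~ (1 - 0.05)^3 ~ 86%; allow wide sampling slack
  expect_gte(empty, 12L)
})

test_that("agreement summary combines the reproducibility statistics", {
  set.seed(45)
  m1 <- rnorm(40, 9.3, 3)
  m2 <- m1 + rnorm(40, 0, 0.25)
  s <- agreement_summary(replicate_table(m1, m2))
  expect_equal(s$cv_percent,
               100 * mean(abs(m1 - m2)) / (sqrt(2) * mean(c(m1, m2))),
               tolerance = 1e-12)
  expect_gt(s$icc, 0.95)
  expect_true(s$icc_ci95[1] <= s$icc && s$icc <= s$icc_ci95[2])
  expect_lt(s$t_p_value, 0.001)
})

test_that("replicate table validation", {
  expect_error(replicate_table(1:2, 1:2), "at least 3")
  expect_error(replicate_table(1:4, 1:3), "equal length")
  expect_error(replicate_table(c(1, NA, 3), c(1, 2, 3)), "finite")
})
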