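test_that("weighted fit matches the normal-equations oracle", {
  set.seed(11)
  x <- rnorm(20); y <- 1.5 + 0.7 * x + rnorm(20, sd = 0.3)
  v <- runif(20, 0.2, 3)
  fit <- weighted_linear_fit(x, y, v)
  orac <- oracle_wls(x, y, 1 / v)
  expect_equal(fit$slope, orac$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, orac$intercept, tolerance = 1e-10)
  expect_equal(fit$slope_se, orac$slope_se, tolerance = 1e-10)
})

test_that("weighted fit reduces to OLS under equal weights", {
  set.seed(12)
  x <- rnorm(15); y <- 2 - x + rnorm(15)
  wf <- weighted_linear_fit(x, y, rep(2, 15))
  of <- unweighted_fit(x, y)
  expect_equal(wf$slope, of$slope, tolerance = 1e-12)
  expect_equal(wf$p_value, of$p_value, tolerance = 1e-12)
  # weighted Pearson r reduces to ordinary r
  expect_equal(wf$r, cor(x, y), tolerance = 1e-12)
  # invariance to uniform variance scaling
  wf2 <- weighted_linear_fit(x, y, rep(20, 15))
  expect_equal(wf$slope, wf2$slope, tolerance = 1e-12)
  expect_equal(wf$slope_se, wf2$slope_se, tolerance = 1e-12)
})

test_that("collinear points give slope one and perfect correlation", {
  # an exact fit makes lm's summary complain; the point is the algebra
  fit <- suppressWarnings(weighted_linear_fit(0:2, 0:2, rep(1, 3)))
  expect_equal(fit$slope, 1)
  expect_equal(fit$r, 1)
  expect_error(weighted_linear_fit(0:2, 0:2, c(1, 0, 1)), "positive")
  expect_error(weighted_linear_fit(0:1, 0:1, c(1, 1)), "at least 3")
})

test_that("OLS identities hold for the unweighted diagnostics fit", {
  set.seed(13)
  x <- rnorm(200); y <- 2 * x + rnorm(200, sd = 0.5)
  fit <- unweighted_fit(x, y)
  expect_equal(fit$slope, 2, tolerance = 0.1)
  expect_equal(fit$r^2, cor(x, y)^2, tolerance = 1e-12)
  expect_equal(fit$r, fit$r_model, tolerance = 1e-12)
})

test_that("standardized coefficients are unit-free and separable", {
  set.seed(14)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)  # independent predictors
  y <- 0.6 * x1 + rnorm(n, sd = 0.4)
  b <- standardized_multiple_fit(cbind(v1 = x1, v2 = x2), y)
  # rescaling a predictor's units changes nothing
  b_scaled <- standardized_multiple_fit(cbind(v1 = 1000 * x1, v2 = x2), y)
  expect_equal(b$b_s, b_scaled$b_s, tolerance = 1e-10)
  # y depends only on x1: the x2 coefficient is near zero
  expect_equal(b$b_s[2], 0, tolerance = 0.1)
  # orthogonal design: b_s match the standardized simple slopes
  s1 <- unweighted_fit(scale(x1)[, 1], scale(y)[, 1])$slope
  expect_equal(b$b_s[1], s1, tolerance = 0.02)
  expect_error(standardized_multiple_fit(cbind(x1, 2 * x1), y),
               "collinear")
})

test_that("slope comparison flags real differences and nothing else", {
  set.seed(15)
  x <- seq(0, 1, length.out = 40)
  g_same <- list(x = x, y = 3 * x + rnorm(40, sd = 0.05),
                 variances = rep(0.01, 40))
  cmp0 <- compare_slopes(g_same, g_same)
  expect_gt(cmp0$p_difference, 0.5)
  g1 <- list(x = x, y = 1 * x + rnorm(40, sd = 0.01),
             variances = rep(1e-4, 40))
  g2 <- list(x = x, y = 2 * x + rnorm(40, sd = 0.01),
             variances = rep(1e-4, 40))
  cmp <- compare_slopes(g1, g2)
  expect_lt(cmp$p_difference, 1e-6)
  expect_equal(unname(cmp$slopes), c(1, 2), tolerance = 0.05)
  # rescaling both groups by a common constant leaves P unchanged
  g1c <- g1; g2c <- g2
  g1c$y <- 10 * g1$y; g1c$variances <- 100 * g1$variances
  g2c$y <- 10 * g2$y; g2c$variances <- 100 * g2$variances
  cmp_c <- compare_slopes(g1c, g2c, rescale_by_mean = TRUE)
  cmp_r <- compare_slopes(g1, g2, rescale_by_mean = TRUE)
  expect_equal(cmp_c$p_difference, cmp_r$p_difference, tolerance = 1e-9)
  # dividing by the means can reconcile slopes that differ only in scale
  g3 <- list(x = x, y = 5 * (1 * x + 0.5) + rnorm(40, sd = 0.01),
             variances = rep(1e-4, 40))
  g4 <- list(x = x, y = 1 * x + 0.5 + rnorm(40, sd = 0.01),
             variances = rep(1e-4, 40))
  expect_lt(compare_slopes(g3, g4)$p_difference, 1e-6)
  expect_gt(compare_slopes(g3, g4, rescale_by_mean = TRUE)$p_difference,
            0.05)
})

test_that("randomization P values obey the add-one rule and calibrate", {
  expect_equal(randomization_pvalue(10, rep(1, 100)), 1 / 101)
  expect_equal(randomization_pvalue(0.5, rep(1, 100)), 1)
  expect_equal(randomization_pvalue(-10, rep(1, 100)), 1 / 101)
  set.seed(16)
  p <- replicate(1000, randomization_pvalue(rnorm(1), rnorm(99)))
  expect_true(all(p > 0 & p <= 1))
  expect_lt(abs(mean(p) - 0.5), 0.05)
  expect_lt(abs(mean(p < 0.1) - 0.1), 0.04)
})

test_that("significance codes follow the figure-legend convention", {
  expect_equal(significance_code(c(1e-4, 0.005, 0.03, 0.07, 0.5)),
               c("***", "**", "*", ".", ""))
})
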