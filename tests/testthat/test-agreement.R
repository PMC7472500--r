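test_that("pearson validity matches the textbook formula", {
  truth <- c(-90, -45, 0, 45, 90)
  measured <- c(-80, -50, 5, 40, 95)
  res <- pearson_validity(measured, truth)
  # independent hand computation of r on the five points
  mx <- mean(measured); my <- mean(truth)
  r_hand <- sum((measured - mx) * (truth - my)) /
    sqrt(sum((measured - mx)^2) * sum((truth - my)^2))
  expect_lt(abs(res$r - r_hand), 1e-12)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  p_hand <- 2 * stats::pt(-abs(t_hand), 3)
  expect_lt(abs(res$p - p_hand), 1e-12)
  expect_equal(res$n, 5)
})

test_that("pearson r handles exact and reversed agreement", {
  x <- c(1, 2, 4, 8)
  expect_equal(pearson_validity(x, x)$r, 1)
  expect_equal(pearson_validity(-x + 7, x)$r, -1)
  # affine invariance (positive slope)
  set.seed(2)
  a <- stats::rnorm(30); b <- a + stats::rnorm(30, sd = 0.3)
  expect_equal(pearson_validity(3 * a + 11, b)$r,
               pearson_validity(a, b)$r, tolerance = 1e-12)
  expect_error(pearson_validity(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_validity(1:2, 1:2), "at least 3")
  expect_error(pearson_validity(1:4, 1:5), "length mismatch")
})

test_that("bland_altman handles exact offsets and exact agreement", {
  truth <- c(-10, 0, 10, 20)
  res <- bland_altman(truth + 5, truth)
  expect_equal(res$bias, 5)
  expect_equal(res$sd_diff, 0)
  expect_equal(c(res$loa_lower, res$loa_upper), c(5, 5))
  expect_true(res$fixed_bias)
  expect_false(res$proportional_bias)
  expect_equal(classify_bias(res), "fixed")
  res0 <- bland_altman(truth, truth)
  expect_equal(res0$bias, 0)
  expect_false(res0$fixed_bias)
  expect_equal(classify_bias(res0), "none")
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("bland_altman recovers known generative parameters", {
  set.seed(1234)
  n <- 200
  truth <- stats::runif(n, -45, 45)
  measured <- truth + stats::rnorm(n, mean = 2, sd = 1)
  res <- bland_altman(measured, truth)
  se <- 1 / sqrt(n)
  expect_lt(abs(res$bias - 2), 2 * se)
  loa_width <- res$loa_upper - res$loa_lower
  expect_lt(abs(loa_width - 3.92) / 3.92, 0.15)
  expect_true(res$fixed_bias)
  expect_false(res$proportional_bias)
})

test_that("the bias estimator is unbiased over seeded replicates", {
  set.seed(77)
  n <- 37
  reps <- 500
  biases <- vapply(seq_len(reps), function(i) {
    truth <- seq(-90, 90, length.out = n)
    bland_altman(truth + stats::rnorm(n, mean = 1.5, sd = 1), truth)$bias
  }, numeric(1))
  se_mean <- 1 / sqrt(n) / sqrt(reps)
  expect_lt(abs(mean(biases) - 1.5), 3 * se_mean)
})

test_that("about 95% of Gaussian differences fall inside the LoA", {
  set.seed(55)
  n <- 2000
  truth <- stats::runif(n, -45, 45)
  res <- bland_altman(truth + stats::rnorm(n), truth)
  # binomial tolerance band around 0.95 (LoA estimated from the sample)
  expect_gt(res$inside_loa, 0.95 - 3 * sqrt(0.95 * 0.05 / n) - 0.005)
  expect_lt(res$inside_loa, 0.95 + 3 * sqrt(0.95 * 0.05 / n) + 0.005)
})

test_that("proportional bias is detected from a slope in the differences", {
  set.seed(99)
  n <- 100
  truth <- seq(-45, 45, length.out = n)
  measured <- truth + 0.1 * truth + stats::rnorm(n, sd = 0.5)
  res <- bland_altman(measured, truth)
  expect_true(res$proportional_bias)
  expect_equal(res$slope, 0.1, tolerance = 0.25)
  expect_true(classify_bias(res) %in% c("proportional",
                                        "fixed+proportional"))
})

test_that("bias classification covers all four flag combinations", {
  base <- bland_altman(c(1, 2, 3) + 0.5, c(1, 2, 3))
  cases <- list(c(FALSE, FALSE, "none"), c(TRUE, FALSE, "fixed"),
                c(FALSE, TRUE, "proportional"),
                c(TRUE, TRUE, "fixed+proportional"))
  for (cs in cases) {
    b <- base
    b$fixed_bias <- as.logical(cs[1])
    b$proportional_bias <- as.logical(cs[2])
    expect_equal(classify_bias(b), cs[3])
  }
})

test_that("peak comparisons match the pooled-variance hand formula", {
  a <- c(12.1, 14.3, 13.8, 15.2, 11.9)
  b <- c(16.4, 17.1, 15.8, 18.0)
  res <- compare_peaks(a, b)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_lt(abs(res$t - t_hand), 1e-10)
  expect_equal(res$df, length(a) + length(b) - 2)
  expect_equal(res$p, 2 * stats::pt(-abs(t_hand), res$df), tolerance = 1e-12)
})

test_that("degenerate and obvious peak comparisons behave by convention", {
  expect_equal(compare_peaks(c(1, 2, 3), c(1, 2, 3))$t, 0)
  same <- compare_peaks(rep(2, 3), rep(2, 4))
  expect_equal(same$p, 1)
  expect_false(same$degenerate)
  shifted <- compare_peaks(c(1, 2, 3), c(11, 12, 13))
  expect_true(shifted$significant)
  degen <- compare_peaks(rep(1, 3), rep(2, 3))
  expect_true(degen$degenerate)
  expect_error(compare_peaks(1, c(1, 2)), "at least 2")
})

test_that("the validity report tabulates every requested cell", {
  rep <- dummy_foot_validity(models = c("new", "rizzoli"),
                             planes = c("frontal", "sagittal"),
                             grid = seq(-60, 60, 15))
  expect_equal(nrow(rep), 2 * 2 * 2)  # models x joints x planes
  expect_true(all(rep$n == 9))
  expect_true(all(rep$loa_lower <= rep$bias & rep$bias <= rep$loa_upper))
  expect_error(validity_report(list()), "empty")
})

test_that("an ideal noiseless sweep validates the new model end to end", {
  rep <- dummy_foot_validity(models = "new")
  expect_true(all(rep$r >= 0.999))
  expect_true(all(rep$bias_class %in% c("fixed", "none")))
})
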