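test_that("Rubin's rules reproduce hand-computed pooling", {
  p <- rubin_pool(c(1, 2, 3, 4, 5), rep(1, 5))
  expect_equal(p$estimate, 3)
  expect_equal(p$W, 1)
  expect_equal(p$B, 2.5)
  expect_equal(p$T, 4.0)
  expect_equal(p$lambda, 0.75)

  p2 <- rubin_pool(c(0, 1), c(1, 1))
  expect_equal(p2$estimate, 0.5)
  expect_equal(p2$W, 1)
  expect_equal(p2$B, 0.5)
  expect_equal(p2$T, 1.75)
  expect_equal(p2$lambda, 0.75 / 1.75, tolerance = 1e-12)  # ~0.4286

  # identical estimates: no between-imputation variance
  p3 <- rubin_pool(rep(2.2, 4), rep(0.3, 4))
  expect_equal(p3$B, 0)
  expect_equal(p3$lambda, 0)
  expect_equal(p3$T, p3$W)

  expect_error(rubin_pool(c(1, 2), c(1, -1)), "negative")
  expect_error(rubin_pool(1, 1), "m >= 2")
})

test_that("total variance obeys T = W + 1.2 B at m = 5 for every pooled term", {
  set.seed(41)
  est <- matrix(stats::rnorm(5 * 7), 5, 7)
  vars <- matrix(stats::rexp(5 * 7), 5, 7)
  p <- rubin_pool(est, vars)
  expect_equal(p$T, p$W + 1.2 * p$B, tolerance = 1e-12)
  expect_true(all(p$T >= p$W))
  expect_true(all(p$lambda >= 0 & p$lambda < 1))
})

test_that("bootstrap matches exhaustive resampling on a 6-row mean fixture", {
  y <- c(1.2, 3.4, 2.2, 5.1, 4.4, 0.7)
  d <- data.frame(y = y)
  mean_fitter <- function(formula, data) {
    list(coefficients = c(mean = mean(data$y)))
  }
  # exhaustive enumeration of all 6^6 with-replacement resamples
  idx <- as.matrix(expand.grid(rep(list(1:6), 6)))
  all_means <- rowMeans(matrix(y[idx], nrow = nrow(idx)))
  enum_mean <- mean(all_means)
  enum_var <- mean((all_means - enum_mean)^2)
  expect_equal(enum_mean, mean(y), tolerance = 1e-12)  # closed form

  bc <- bootstrap_coefficients(d, y ~ 1, mean_fitter, B = 4000, seed = 42)
  mc_se <- sqrt(enum_var / 4000)
  expect_lt(abs(bc$estimate[["mean"]] - enum_mean), 4 * mc_se)
  expect_lt(abs(bc$vcov[1, 1] - enum_var), 0.15 * enum_var)
})

test_that("degenerate data give zero bootstrap variance", {
  d <- data.frame(y = rep(0.4, 30))
  suppressWarnings(
    bc <- bootstrap_coefficients(d, y ~ 1, fitter_beta(), B = 20, seed = 1))
  expect_equal(unname(bc$vcov[1, 1]), 0)
})

test_that("two bootstrap seeds agree within Monte-Carlo error", {
  d <- make_truth_frame(800, seed = 43)
  f <- vas_t ~ age + exp_self
  b1 <- bootstrap_coefficients(d, f, fitter_beta(), B = 500, seed = 7)
  b2 <- bootstrap_coefficients(d, f, fitter_beta(), B = 500, seed = 8)
  se <- sqrt(diag(b1$vcov) / 500 + diag(b2$vcov) / 500)
  expect_true(all(abs(b1$estimate - b2$estimate) < 3 * se))
})

test_that("pooled coefficients are scale-equivariant", {
  d <- make_truth_frame(600, seed = 44)
  d$age10 <- d$age / 10
  b1 <- bootstrap_coefficients(d, vas_t ~ age, fitter_beta(), B = 150,
                               seed = 5)
  b2 <- bootstrap_coefficients(d, vas_t ~ age10, fitter_beta(), B = 150,
                               seed = 5)
  expect_equal(b2$estimate[["age10"]], 10 * b1$estimate[["age"]],
               tolerance = 1e-5)
  expect_equal(b2$vcov["age10", "age10"], 100 * b1$vcov["age", "age"],
               tolerance = 1e-4)
})

test_that("with no missing data the pooled fit equals the single fit", {
  d <- make_truth_frame(500, seed = 45)
  imp <- impute_fcs(d, imputation_plan(d, m = 3, seed = 2,
                                       restricted = list()))
  f <- vas_t ~ age + exp_self
  # imputing a complete table yields identical datasets, so the pooled
  # estimate collapses onto the single complete-data fit with B = 0
  fits <- lapply(imp$datasets, function(dk) fit_beta_regression(f, dk))
  est <- do.call(rbind, lapply(fits, coef))
  vars <- do.call(rbind, lapply(fits, function(ft) diag(vcov(ft))))
  pooled <- rubin_pool(est, vars)
  single <- fit_beta_regression(f, d)
  expect_equal(pooled$B, rep(0, 3))
  expect_equal(pooled$lambda, rep(0, 3))
  expect_equal(pooled$estimate, unname(coef(single)))
  expect_equal(pooled$W, unname(diag(vcov(single))))

  # same holds on the bootstrap route when the resampling seed is shared
  bcs <- lapply(imp$datasets, function(dk) {
    bootstrap_coefficients(dk, f, fitter_beta(), B = 40, seed = 3)
  })
  pb <- rubin_pool(do.call(rbind, lapply(bcs, `[[`, "estimate")),
                   do.call(rbind, lapply(bcs, function(b) diag(b$vcov))))
  expect_equal(pb$B, rep(0, 3))
  expect_equal(pb$lambda, rep(0, 3))
})

test_that("stratified resampling preserves stratum sizes", {
  d <- make_truth_frame(300, seed = 46)
  d$stratum <- factor(rep(c("a", "b", "c"), each = 100))
  count_fitter <- function(formula, data) {
    list(coefficients = c(n_a = sum(data$stratum == "a")))
  }
  bc <- bootstrap_coefficients(d, vas_t ~ 1, count_fitter, B = 25, seed = 9,
                               strata = d$stratum)
  expect_true(all(bc$replicates[, "n_a"] == 100))
})
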