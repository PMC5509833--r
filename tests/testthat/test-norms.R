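test_that("age-only norm fits require a non-degenerate age design", {
  d <- make_cohort(300, seed = 51)
  fits <- fit_age_norms(list(d), "vas_t", "beta")
  expect_s3_class(fits[[1]], "qn_beta")
  expect_true(all(c("age", "I(age^2)") %in%
                    attr(stats::terms(fits[[1]]$formula), "term.labels")))
  d$age <- 40L
  expect_error(fit_age_norms(list(d), "vas_t", "beta"), "I\\(age\\^2\\)")
})

test_that("norm curves respect bounds and contain their point estimate", {
  d <- make_cohort(1200, seed = 52)
  spec <- attr(d, "spec")
  expect_warning(
    nc <- predict_norms_ci(list(d), "vas_t", spec, "beta", ages = 0:110,
                           B = 40, seed = 1),
    "extrapolat")
  cv <- nc$curves$vas
  expect_true(all(cv$lo <= cv$fit & cv$fit <= cv$hi))
  expect_true(all(cv$lo >= 0 & cv$hi <= 100))

  nce <- predict_norms_ci(list(d), "eq5d_t", spec, "oneinflated",
                          ages = seq(0, 99, 3), B = 40, seed = 2)
  expect_setequal(names(nce$curves), c("p_one", "cond_index", "mean_index"))
  p1 <- nce$curves$p_one
  expect_true(all(p1$lo >= 0 & p1$hi <= 1))
  expect_true(all(p1$lo <= p1$fit & p1$fit <= p1$hi))
  mi <- nce$curves$mean_index
  expect_true(all(mi$hi <= 1 + 1e-9))
})

test_that("a quadratic age truth is recovered by the norm curve", {
  cfg <- truth_config(
    n = 3000,
    vas_coefs = c(intercept = 1.25, age = 0.03, age2 = -3e-4),
    nu_coefs = c(intercept = 0.9, age = 0.04, age2 = -7e-4),
    mu_coefs = c(intercept = 2.63, age = -0.02),
    missing_rates = numeric(0), seed = 53)
  d <- make_cohort(3000, seed = 53, cfg = cfg)
  spec <- attr(d, "spec")
  nc <- predict_norms_ci(list(d), "vas_t", spec, "beta", ages = c(10, 40, 80),
                         B = 120, seed = 3)
  cv <- nc$curves$vas
  truth_vas <- 100 * stats::plogis(1.25 + 0.03 * cv$age - 3e-4 * cv$age^2)
  expect_true(all(cv$lo - 2 <= truth_vas & truth_vas <= cv$hi + 2))
  expect_lt(max(abs(cv$mean_fit - truth_vas)), 3)

  nce <- predict_norms_ci(list(d), "eq5d_t", spec, "oneinflated",
                          ages = c(10, 40, 80), B = 120, seed = 4)
  p1 <- nce$curves$p_one
  truth_p1 <- stats::plogis(0.9 + 0.04 * p1$age - 7e-4 * p1$age^2)
  expect_lt(max(abs(p1$mean_fit - truth_p1)), 0.06)
})

test_that("the confidence band collapses in the zero-noise limit", {
  cfg <- truth_config(
    n = 2000,
    vas_coefs = c(intercept = 1.0, age = 0.01),
    vas_precision = 1e6, missing_rates = numeric(0), seed = 54)
  d <- make_cohort(2000, seed = 54, cfg = cfg)
  nc <- predict_norms_ci(list(d), "vas_t", attr(d, "spec"), "beta",
                         ages = c(20, 50, 80), B = 60, seed = 5)
  expect_lt(max(nc$curves$vas$hi - nc$curves$vas$lo), 0.5)
})

test_that("bands from two seeds agree within Monte-Carlo tolerance", {
  d <- make_cohort(1000, seed = 55)
  spec <- attr(d, "spec")
  n1 <- predict_norms_ci(list(d), "vas_t", spec, "beta", ages = c(20, 60),
                         B = 300, seed = 6)
  n2 <- predict_norms_ci(list(d), "vas_t", spec, "beta", ages = c(20, 60),
                         B = 300, seed = 7)
  expect_lt(max(abs(n1$curves$vas$fit - n2$curves$vas$fit)), 1)
  expect_lt(max(abs(n1$curves$vas$lo - n2$curves$vas$lo)), 2)
  expect_lt(max(abs(n1$curves$vas$hi - n2$curves$vas$hi)), 2)
})
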