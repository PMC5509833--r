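test_that("beta log-density matches closed forms and normalizes", {
  # mu = 1/2, phi = 2 is Beta(1, 1): uniform, log-density 0 everywhere
  expect_equal(beta_logpdf(c(0.1, 0.5, 0.93), 0.5, 2), rep(0, 3))
  # mu = 1/2, phi = 4 is Beta(2, 2): density at 1/2 is 1.5
  expect_equal(beta_logpdf(0.5, 0.5, 4), log(1.5))
  int <- stats::integrate(function(y) exp(beta_logpdf(y, 0.3, 7)), 0, 1,
                          rel.tol = 1e-10)
  expect_equal(int$value, 1, tolerance = 1e-8)
  expect_error(beta_logpdf(0, 0.5, 2), "strictly")
  expect_error(beta_logpdf(0.5, 0.5, -1), "phi")
})

test_that("gamlss sigma mapping round-trips exactly", {
  phi <- c(0.5, 1, 5, 42.42)
  expect_equal(sigma_to_phi(phi_to_sigma(phi)), phi, tolerance = 1e-12)
  expect_equal(phi_to_sigma(3), sqrt(1 / 4))
})

test_that("analytic score matches central finite differences", {
  set.seed(11)
  n <- 60
  X <- cbind(1, stats::rnorm(n), stats::runif(n))
  y <- stats::rbeta(n, 2, 3)
  ly <- log(y); l1y <- log1p(-y); ystar <- ly - l1y
  for (rep in 1:5) {
    par <- c(stats::rnorm(3, 0, 0.5), stats::rnorm(1, 1, 0.3))
    g <- qolnorm:::.beta_score(par, X, y, ystar, l1y)
    h <- 1e-6
    g_num <- vapply(seq_along(par), function(j) {
      e <- numeric(4); e[j] <- h
      (qolnorm:::.beta_ll(par + e, X, y, ly, l1y) -
         qolnorm:::.beta_ll(par - e, X, y, ly, l1y)) / (2 * h)
    }, numeric(1))
    expect_equal(g, g_num, tolerance = 1e-6)
  }
})

test_that("beta regression recovers simulated coefficients within 3 SEs", {
  set.seed(12)
  n <- 5000
  age <- sample(0:99, n, TRUE)
  truth <- c(1.25, 0.03, -3e-4)
  mu <- stats::plogis(truth[1] + truth[2] * age + truth[3] * age^2)
  phi <- 6
  d <- data.frame(age = age,
                  y = stats::rbeta(n, mu * phi, (1 - mu) * phi))
  fit <- fit_beta_regression(y ~ age + I(age^2), d)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(abs(coef(fit) - truth) < 3 * se))
  expect_lt(abs(fit$phi - phi), 3 * sqrt(vcov(fit, full = TRUE)["log(phi)",
                                              "log(phi)"]) * fit$phi)
  # likelihood ascent is monotone by construction
  expect_true(all(diff(fit$loglik_trace) >= -1e-10))
})

test_that("degenerate and ill-posed designs are caught", {
  d <- data.frame(y = rep(0.37, 40), x = stats::rnorm(40))
  expect_warning(fit <- fit_beta_regression(y ~ 1, d), "constant")
  expect_equal(stats::plogis(coef(fit)[[1]]), 0.37, tolerance = 1e-8)

  d2 <- data.frame(y = stats::rbeta(30, 2, 2), x = 1:30)
  d2$z <- 2 * d2$x
  expect_error(fit_beta_regression(y ~ x + z, d2), "aliased.*z")
})

test_that("one-inflated likelihood factorizes exactly into nu and mu parts", {
  d <- make_cohort(800, seed = 13)
  oi <- fit_one_inflated(eq5d_t ~ age + exp_self, eq5d_t ~ age + exp_self, d)
  # independent refits of the two parts
  d$.one <- as.integer(d$eq5d_t == 1)
  nu <- stats::glm(.one ~ age + exp_self, binomial(), d)
  mu <- fit_beta_regression(eq5d_t ~ age + exp_self, d[d$eq5d_t != 1, ])
  expect_equal(oi$loglik, as.numeric(stats::logLik(nu)) + mu$loglik,
               tolerance = 1e-8)
  expect_equal(unname(coef(oi$nu)), unname(coef(nu)), tolerance = 1e-8)

  # intercept-only nu model: fitted probability is the sample one-fraction
  oi0 <- fit_one_inflated(eq5d_t ~ 1, eq5d_t ~ 1, d)
  expect_equal(stats::plogis(coef(oi0$nu)[[1]]), mean(d$eq5d_t == 1),
               tolerance = 1e-8)
  expect_equal(unique(round(predict(oi0, d, type = "p_one"), 10)),
               round(mean(d$eq5d_t == 1), 10))

  dbad <- d; dbad$eq5d_t <- 1
  expect_error(fit_one_inflated(eq5d_t ~ 1, eq5d_t ~ 1, dbad), "degenerate")
})

test_that("Cox-Snell pseudo-R2 follows its formula", {
  expect_equal(cox_snell_r2(-100, -100, 50), 0)
  expect_equal(cox_snell_r2(-90, -100, 100), 1 - exp(-0.2))
  expect_error(cox_snell_r2(-90, -100, 0), "positive")
  expect_error(cox_snell_r2(-101, -100, 10), "nested")
})

test_that("randomized quantile residuals are standard normal under the truth", {
  d <- make_truth_frame(10000, seed = 14)
  oi <- fit_one_inflated(
    eq5d_t ~ age + age2 + sick + exp_self + exp_family + pets,
    eq5d_t ~ age + exp_self + exp_family + child + disabled + smoking, d)
  r1 <- rq_residuals(oi, seed = 7)
  r2 <- rq_residuals(oi, seed = 7)
  expect_identical(r1, r2)
  ks <- suppressWarnings(stats::ks.test(r1, "pnorm"))
  expect_lt(unname(ks$statistic), 1.358 / sqrt(length(r1)))

  # a non-inflated observation at its fitted median has residual zero
  fit <- fit_beta_regression(vas_t ~ 1, d)
  mu <- fit$fitted.values[1]
  ymed <- stats::qbeta(0.5, mu * fit$phi, (1 - mu) * fit$phi)
  fit$y[1] <- ymed
  expect_equal(rq_residuals(fit)[1], 0, tolerance = 1e-8)
})

test_that("predictions are consistent on and off the original scale", {
  d <- make_cohort(1500, seed = 15)
  spec <- attr(d, "spec")
  fit <- fit_beta_regression(vas_t ~ age + I(age^2) + exp_self, d)
  expect_equal(predict(fit, newdata = d), unname(fit$fitted.values),
               tolerance = 1e-10)
  vas_hat <- predict_outcome(fit, d, spec)
  expect_equal(vas_hat, backtransform_vas(fit$fitted.values, spec),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(vas_hat > 0 & vas_hat < 100))

  oi <- fit_one_inflated(eq5d_t ~ age + exp_self, eq5d_t ~ age + exp_self, d)
  p <- predict_outcome(oi, d, spec)
  expect_true(all(p$p_one > 0 & p$p_one < 1))
  expect_true(all(p$cond_index > spec$min_index - 1e-9 &
                    p$cond_index < 1))
  expect_equal(p$mean_index, p$p_one + (1 - p$p_one) * p$cond_index)
  expect_warning(predict_outcome(fit, data.frame(age = 150,
                                                 exp_self = "no"),
                                 spec, age_range = c(0, 99)),
                 "extrapolation")
})

test_that("outlier flagging uses the 3.5-residual rule", {
  d <- make_cohort(400, seed = 16)
  fit <- fit_beta_regression(vas_t ~ age, d)
  fl <- flag_outliers(fit, seed = 1)
  expect_type(fl, "logical")
  expect_identical(fl, abs(rq_residuals(fit, seed = 1)) > 3.5)
})
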