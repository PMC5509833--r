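test_that("elimination stops immediately when everything is significant", {
  d <- make_truth_frame(1500, seed = 31)
  sel <- backward_eliminate(list(d), vas_t ~ age + age2 + exp_self + sick,
                            fitter_beta(), forced = c("age", "age2"))
  expect_equal(nrow(sel$history), 0)
  expect_equal(sort(attr(stats::terms(sel$formula), "term.labels")),
               sort(c("age", "age2", "exp_self", "sick")))
})

test_that("noise terms are dropped, forced terms never are", {
  set.seed(32)
  d <- make_truth_frame(1200, seed = 33)
  d$noise <- stats::rnorm(nrow(d))
  sel <- backward_eliminate(
    list(d, d), vas_t ~ age + age2 + exp_self + sick + noise,
    fitter_beta(), forced = c("age", "age2"))
  labs <- attr(stats::terms(sel$formula), "term.labels")
  expect_false("noise" %in% labs)
  expect_true(all(c("age", "age2") %in% labs))

  # even a pure-noise forced term survives
  d$forcedjunk <- stats::rnorm(nrow(d))
  sel2 <- backward_eliminate(
    list(d), vas_t ~ age + age2 + forcedjunk, fitter_beta(),
    forced = c("age", "age2", "forcedjunk"))
  expect_true("forcedjunk" %in%
                attr(stats::terms(sel2$formula), "term.labels"))

  # identical inputs give identical selection paths
  sel3 <- backward_eliminate(
    list(d, d), vas_t ~ age + age2 + exp_self + sick + noise,
    fitter_beta(), forced = c("age", "age2"))
  expect_identical(sel$history, sel3$history)
  expect_identical(deparse(sel$formula), deparse(sel3$formula))
})

test_that("elimination can empty the model gracefully", {
  set.seed(34)
  d <- data.frame(y = stats::rbeta(300, 2, 2), x = stats::rnorm(300))
  expect_warning(sel <- backward_eliminate(list(d), y ~ x, fitter_beta()),
                 "intercept-only")
  expect_equal(length(attr(stats::terms(sel$formula), "term.labels")), 0)
})

test_that("merging equal-effect levels wins on AIC, invariant to reference", {
  set.seed(35)
  n <- 2500
  g <- factor(sample(c("a", "b", "c"), n, TRUE))
  eff <- c(a = 0, b = 0.4, c = 0.4)[as.character(g)]  # b and c identical
  mu <- stats::plogis(0.3 + eff)
  d <- data.frame(g = g, y = stats::rbeta(n, mu * 8, (1 - mu) * 8))
  rc <- recategorize_aic(list(d), y ~ g, fitter_beta(), "g",
                         merges = list(c(b = "bc", c = "bc"),
                                       c(a = "ab", b = "ab")))
  # the equal-effect merge beats the wrong merge, and the original coding
  # can only ever beat it by chance, never by more than the 2-AIC penalty
  expect_true(rc$best %in% c("merge_1", "original"))
  expect_lt(rc$aic[["merge_1"]], rc$aic[["merge_2"]])
  expect_true(rc$ref_invariant)
  drop_aic <- rc$aic[["original"]] - rc$aic[["merge_1"]]
  expect_lte(drop_aic, 2 + 1e-8)
  expect_gt(drop_aic, 2 - 2 * stats::qchisq(0.999, 1))

  # AIC of the unmerged model is identical under every reference category
  for (rf in c("a", "b", "c")) {
    d2 <- d
    d2$g <- stats::relevel(d2$g, rf)
    expect_equal(stats::AIC(fit_beta_regression(y ~ g, d2)),
                 rc$aic[["original"]], tolerance = 1e-6)
  }
})

test_that("factor terms are tested as blocks during elimination", {
  set.seed(36)
  n <- 1000
  g <- factor(sample(c("a", "b", "c", "d"), n, TRUE))
  mu <- stats::plogis(0.5)  # factor is pure noise
  d <- data.frame(g = g, x = stats::rnorm(n))
  d$y <- stats::rbeta(n, stats::plogis(0.5 + 0.5 * d$x) * 6,
                      (1 - stats::plogis(0.5 + 0.5 * d$x)) * 6)
  sel <- backward_eliminate(list(d), y ~ x + g, fitter_beta())
  labs <- attr(stats::terms(sel$formula), "term.labels")
  expect_true("x" %in% labs)
  # the whole factor leaves as one unit if it leaves
  if (!"g" %in% labs) {
    expect_false(any(grepl("^g", labs)))
  }
})
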