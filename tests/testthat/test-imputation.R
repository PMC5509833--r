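test_that("a complete table passes through imputation unchanged", {
  d <- make_cohort(200, seed = 21)
  plan <- imputation_plan(d, m = 3, seed = 1)
  imp <- impute_fcs(d, plan)
  expect_length(imp$datasets, 3)
  for (k in 1:3) expect_identical(imp$datasets[[k]], d)
})

test_that("observed cells are preserved and no missing cells remain", {
  d <- make_cohort(600, seed = 22)
  dm <- inject_missingness(d, seed = 23)
  plan <- imputation_plan(dm, m = 3, burn_in = 3, seed = 5)
  imp <- suppressWarnings(impute_fcs(dm, plan))
  obs <- !is.na(dm$vas)
  for (k in 1:3) {
    dk <- imp$datasets[[k]]
    expect_identical(dk$vas[obs], dm$vas[obs])
    expect_identical(dk$exp_family[!is.na(dm$exp_family)],
                     dm$exp_family[!is.na(dm$exp_family)])
    # every maskable cell filled; restricted variable blanked off-subgroup
    expect_false(anyNA(dk$vas))
    expect_false(anyNA(dk$exp_self))
    expect_false(anyNA(dk$n_grandchildren[dk$group == "elderly"]))
    expect_true(all(is.na(dk$n_grandchildren[dk$group != "elderly"])))
    # subgroup factors keep their by-design "irrelevant" level
    expect_true(all(dk$smoking[dk$group == "child"] == "irrelevant"))
    expect_true(all(dk$smoking[dk$group != "child"] != "irrelevant"))
    # PMM imputations live in the observed support
    expect_true(all(dk$vas[!obs] %in% dm$vas[obs]))
  }
})

test_that("PMM donor selection is nearest-k and uniform among ties", {
  # unique nearest donor with donor_k = 1 is deterministic
  y <- c(10, 20, 30, 40)
  pred <- c(1, 2, 3, 4)
  expect_equal(pmm_draw(y, pred, 2.1, donor_k = 1), 20)
  # identical predictions: uniform draw over all donors
  set.seed(3)
  draws <- replicate(10000, pmm_draw(y, rep(1, 4), 1, donor_k = 4))
  expect_true(all(draws %in% y))
  chi <- stats::chisq.test(table(factor(draws, levels = y)))
  expect_gt(chi$p.value, 0.001)
  # donor pool shrinks with a warning when too few donors
  expect_warning(v <- pmm_draw(c(5, 7), c(0, 1), 0.2, donor_k = 5),
                 "reducing pool")
  expect_true(v %in% c(5, 7))
})

test_that("constant observed variables impute as the constant with warning", {
  d <- data.frame(x = c(rep(2.5, 8), NA, NA), z = stats::rnorm(10),
                  w = stats::rbeta(10, 2, 2))
  plan <- imputation_plan(d, m = 2, burn_in = 2, seed = 1,
                          predictors = c("x", "z", "w"), restricted = list())
  expect_warning(imp <- impute_fcs(d, plan), "constant")
  expect_true(all(imp$datasets[[1]]$x == 2.5))
})

test_that("chain-drift diagnostics flag trends but not stationary noise", {
  # constant trace: never flagged
  tr <- array(1, dim = c(3, 6, 1), dimnames = list(NULL, NULL, "v"))
  expect_false(check_convergence(tr)$flagged)
  # injected linear drift in all chains: flagged
  drift <- array(rep(seq(0, 5, length.out = 6), each = 3) +
                   stats::rnorm(18, 0, 0.01),
                 dim = c(3, 6, 1), dimnames = list(NULL, NULL, "v"))
  expect_true(check_convergence(drift)$flagged)
  # a default 5-iteration run on a synthetic cohort is not flagged
  d <- make_cohort(500, seed = 24)
  dm <- inject_missingness(d, seed = 25)
  imp <- suppressWarnings(impute_fcs(dm, imputation_plan(dm, m = 3,
                                                         seed = 6)))
  cc <- check_convergence(imp)
  expect_true(all(!cc$flagged[cc$variable %in% c("vas", "eq5d_index")]))
})

test_that("burn-in length does not move the imputed-value distribution", {
  d <- make_cohort(500, seed = 26)
  dm <- inject_missingness(d, missing_rates = c(vas = 0.15), seed = 27)
  means <- vapply(c(5, 20), function(bi) {
    imp <- suppressWarnings(impute_fcs(
      dm, imputation_plan(dm, m = 2, burn_in = bi, seed = 9)))
    mean(vapply(imp$datasets, function(dk) {
      mean(dk$vas[is.na(dm$vas)])
    }, numeric(1)))
  }, numeric(1))
  # agreement within Monte-Carlo noise of the imputed-cell mean
  mc <- stats::sd(d$vas) / sqrt(sum(is.na(dm$vas)))
  expect_lt(abs(diff(means)), 4 * mc)
})

test_that("tree-based imputation stays in the observed support", {
  d <- make_cohort(500, seed = 28)
  dm <- inject_missingness(d, missing_rates = c(pets = 0.1), seed = 29)
  plan <- imputation_plan(dm, methods = c(pets = "cart"), m = 2,
                          burn_in = 2, seed = 11)
  imp <- suppressWarnings(impute_fcs(dm, plan))
  filled <- imp$datasets[[1]]$pets[is.na(dm$pets)]
  expect_true(all(filled %in% c("yes", "no")))
})
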