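#' Predictions on the original outcome scale
#'
#' Maps fitted values back through the transform chain: for a VAS beta fit,
#' \eqn{100 \times} the inverse shrink of the fitted mean; for a
#' one-inflated EQ-5D fit, the perfect-health probability \eqn{p_1}, the
#' conditional mean back through the shrink and normalization inverses, and
#' the overall mean index \eqn{p_1 + (1 - p_1)\,E[\mathrm{index} \mid
#' \mathrm{index} < 1]}.
#'
#' @param fit a `qn_beta` (VAS) or `qn_oibeta` (EQ-5D) fit.
#' @param newdata rows to predict for (default: the training rows).
#' @param spec the [transform_spec()] used to transform the outcome.
#' @param age_range observed age range; predictions outside it warn.
#' @return for `qn_beta`: numeric VAS predictions (0-100); for
#'   `qn_oibeta`: data frame with `p_one`, `cond_index`, `mean_index`.
#' @export
predict_outcome <- function(fit, newdata = NULL, spec, age_range = NULL) {
  stopifnot(inherits(spec, "qn_transform_spec"))
  if (!is.null(age_range) && !is.null(newdata) && "age" %in% names(newdata)) {
    if (any(newdata$age < age_range[1] | newdata$age > age_range[2])) {
      warning("predicting outside the observed age range [",
              age_range[1], ", ", age_range[2], "]: extrapolation")
    }
  }
  if (inherits(fit, "qn_beta")) {
    mu <- predict(fit, newdata = newdata, type = "response")
    return(backtransform_vas(mu, spec))
  }
  if (inherits(fit, "qn_oibeta")) {
    p1 <- predict(fit, newdata = newdata, type = "p_one")
    mu <- if (is.null(newdata)) predict(fit, newdata = fit$nu$data,
                                        type = "cond_mean")
          else predict(fit, newdata = newdata, type = "cond_mean")
    cond <- denormalize_index(inverse_shrink(mu, spec$n),
                              spec$min_index, spec$max_index)
    return(data.frame(p_one = p1, cond_index = cond,
                      mean_index = p1 + (1 - p1) * cond))
  }
  stop("predict_outcome: unsupported fit class")
}

#' Fit age-only norm models on an imputed stack
#'
#' Fits the population-norm model — intercept, age and age squared in every
#' submodel — to each completed dataset: a beta regression for (transformed)
#' VAS, or a one-inflated beta regression (nu and mu parts both quadratic in
#' age) for the transformed EQ-5D index.
#'
#' @param stacks `qn_imputed` object or list of completed data frames.
#' @param outcome name of the transformed outcome column (e.g. `"vas_t"` or
#'   `"eq5d_t"`).
#' @param type `"beta"` (VAS-style) or `"oneinflated"` (EQ-5D-style).
#' @return list of per-dataset fits.
#' @export
fit_age_norms <- function(stacks, outcome,
                          type = c("beta", "oneinflated")) {
  type <- match.arg(type)
  datasets <- if (inherits(stacks, "qn_imputed")) stacks$datasets
              else if (is.data.frame(stacks)) list(stacks) else stacks
  f <- stats::as.formula(paste(outcome, "~ age + I(age^2)"))
  lapply(datasets, function(d) {
    if (stats::var(d$age) == 0) {
      stop("age is constant: the quadratic term I(age^2) (and age itself) ",
           "cannot be estimated")
    }
    if (type == "beta") fit_beta_regression(f, d)
    else fit_one_inflated(f, f, d)
  })
}

#' Age-gridded norm curve with bootstrap confidence band
#'
#' For each of the `m` completed datasets, draws `B` bootstrap resamples of
#' the respondent rows, refits the age-only norm model, and predicts the
#' outcome on the original scale over the age grid. The replicate curves
#' from all `m x B` refits are summarized per age by their median (point
#' estimate, guaranteed to lie inside the band) and the 2.5% / 97.5%
#' percentiles (confidence band); the mean of the `m` full-data fits is
#' reported alongside. Ages outside the observed range trigger an
#' extrapolation warning.
#'
#' @param stacks `qn_imputed` or list of completed data frames.
#' @param outcome transformed outcome column name.
#' @param spec the dataset's [transform_spec()].
#' @param type `"beta"` or `"oneinflated"`.
#' @param ages age grid (default 0-99).
#' @param B bootstrap replicates per dataset (default 500).
#' @param seed base seed.
#' @param conf_level band coverage (default 0.95).
#' @return object of class `qn_normcurve`: data frame with `age`, `fit`
#'   (bootstrap median), `mean_fit` (full-data pooled mean), `lo`, `hi`;
#'   for one-inflated outcomes one such frame per component (`p_one`,
#'   `cond_index`, `mean_index`), stored as a named list.
#' @export
predict_norms_ci <- function(stacks, outcome, spec,
                             type = c("beta", "oneinflated"),
                             ages = 0:99, B = 500L, seed = 1L,
                             conf_level = 0.95) {
  type <- match.arg(type)
  datasets <- if (inherits(stacks, "qn_imputed")) stacks$datasets
              else if (is.data.frame(stacks)) list(stacks) else stacks
  m <- length(datasets)
  obs_age <- range(datasets[[1]]$age)
  if (any(ages < obs_age[1] | ages > obs_age[2])) {
    warning("age grid extends beyond observed ages [", obs_age[1], ", ",
            obs_age[2], "]: extrapolating")
  }
  grid <- data.frame(age = ages)
  f <- stats::as.formula(paste(outcome, "~ age + I(age^2)"))
  predict_curve <- function(fit) {
    if (type == "beta") {
      matrix(predict_outcome(fit, grid, spec), nrow = 1,
             dimnames = list("vas", NULL))
    } else {
      p <- predict_outcome(fit, grid, spec)
      t(as.matrix(p))  # rows: p_one, cond_index, mean_index
    }
  }
  fit_one <- function(d) {
    if (type == "beta") fit_beta_regression(f, d) else
      fit_one_inflated(f, f, d)
  }
  full_curves <- lapply(datasets, function(d) predict_curve(fit_one(d)))
  comp <- rownames(full_curves[[1]])
  boot <- array(NA_real_, dim = c(m * B, length(comp), length(ages)))
  r <- 0L
  n_fail <- 0L
  for (d in seq_len(m)) {
    set.seed(seed + d)
    dat <- datasets[[d]]
    n <- nrow(dat)
    for (b in seq_len(B)) {
      r <- r + 1L
      db <- dat[sample.int(n, n, replace = TRUE), , drop = FALSE]
      cb <- tryCatch(suppressWarnings(predict_curve(fit_one(db))),
                     error = function(e) NULL)
      if (is.null(cb)) { n_fail <- n_fail + 1L; next }
      boot[r, , ] <- cb
    }
  }
  if (n_fail > 0.1 * m * B) {
    stop("norm-curve bootstrap: ", n_fail, " of ", m * B,
         " replicate fits failed")
  }
  alpha <- 1 - conf_level
  out <- lapply(seq_along(comp), function(j) {
    bj <- boot[, j, , drop = TRUE]
    if (is.null(dim(bj))) bj <- matrix(bj, ncol = length(ages))
    qs <- apply(bj, 2, stats::quantile,
                probs = c(alpha / 2, 0.5, 1 - alpha / 2), na.rm = TRUE)
    mean_fit <- colMeans(do.call(rbind, lapply(full_curves,
                                               function(fc) fc[j, ])))
    data.frame(age = ages, fit = qs[2, ], mean_fit = mean_fit,
               lo = qs[1, ], hi = qs[3, ], row.names = NULL)
  })
  names(out) <- comp
  structure(list(curves = out, outcome = outcome, type = type, B = B,
                 m = m, n_fail = n_fail, conf_level = conf_level),
            class = "qn_normcurve")
}

#' @export
print.qn_normcurve <- function(x, ...) {
  cat("Norm curve for", x$outcome, "(", x$type, "),", x$m, "x", x$B,
      "bootstrap refits,", x$n_fail, "failed\n")
  for (nm in names(x$curves)) {
    cv <- x$curves[[nm]]
    mid <- cv[round(nrow(cv) / 2), ]
    cat(sprintf("  %s: %.3g [%.3g, %.3g] at age %d\n", nm, mid$fit, mid$lo,
                mid$hi, mid$age))
  }
  invisible(x)
}

#' @export
plot.qn_normcurve <- function(x, component = 1, ...) {
  cv <- x$curves[[component]]
  graphics::plot(cv$age, cv$fit, type = "l", xlab = "age (years)",
                 ylab = names(x$curves)[component],
                 ylim = range(cv$lo, cv$hi), ...)
  graphics::lines(cv$age, cv$lo, lty = 2)
  graphics::lines(cv$age, cv$hi, lty = 2)
  invisible(x)
}
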