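#' Bootstrap coefficient estimates and variance for one dataset
#'
#' Nonparametrically resamples respondent rows with replacement (`n` rows
#' per replicate), refits the model on each replicate, and summarizes the
#' `B` replicate coefficient vectors by their mean (the per-dataset
#' coefficient estimate) and empirical variance-covariance matrix (the
#' per-dataset variance). This is the route of choice when the model's
#' observed-information covariance is unreliable. Replicate fits are warm-
#' started from the full-data coefficients when the fitter supports a
#' `start` argument, falling back to a cold start if the warm fit fails;
#' failed replicates are dropped and counted, and more than `max_fail_frac`
#' failures aborts with diagnostics.
#'
#' @param data a completed (imputed) dataset.
#' @param formula model formula.
#' @param fitter fitter function (see [fitter_beta()]).
#' @param B number of bootstrap replicates (default 500).
#' @param seed RNG seed.
#' @param strata optional factor for stratified resampling (e.g. age group).
#' @param max_fail_frac maximum tolerated fraction of failed replicates.
#' @return list with `estimate` (mean coefficient vector), `vcov`
#'   (empirical covariance over replicates), `replicates` (B x p matrix),
#'   `n_fail`.
#' @export
bootstrap_coefficients <- function(data, formula, fitter = fitter_beta(),
                                   B = 500L, seed = NULL, strata = NULL,
                                   max_fail_frac = 0.1) {
  stopifnot(B >= 2)
  if (!is.null(seed)) set.seed(seed)
  full <- fitter(formula, data)
  cf0 <- stats::coef(full)
  n <- nrow(data)
  idx_draw <- if (is.null(strata)) {
    function() sample.int(n, n, replace = TRUE)
  } else {
    groups <- split(seq_len(n), strata)
    function() unlist(lapply(groups, function(g) {
      g[sample.int(length(g), length(g), replace = TRUE)]
    }), use.names = FALSE)
  }
  reps <- matrix(NA_real_, B, length(cf0),
                 dimnames = list(NULL, names(cf0)))
  takes_start <- "start" %in% names(formals(fitter))
  warm <- if (takes_start && inherits(full, "qn_beta")) {
    coef(full, full = TRUE)
  } else if (takes_start && inherits(full, "glm")) {
    stats::coef(full)
  } else NULL
  # fast path: when the full fit used every row of `data`, a resample's
  # design matrix is just a row-resample of the full design, so refits can
  # skip the formula machinery entirely (numerically the same model)
  refit <- NULL
  if (inherits(full, "qn_beta") && nrow(full$x) == n) {
    Xf <- full$x; yf <- full$y
    refit <- function(idx) {
      # replicate-level tolerance: 1e-8 relative log-likelihood change is
      # far below bootstrap Monte-Carlo noise
      r <- .beta_mle(Xf[idx, , drop = FALSE], yf[idx], start = warm,
                     reltol = 1e-8, compute_vcov = FALSE)
      r$par[seq_along(cf0)]
    }
  } else if (inherits(full, "glm") && length(full$y) == n) {
    Xf <- stats::model.matrix(full); yf <- full$y; fam <- full$family
    refit <- function(idx) {
      r <- stats::glm.fit(Xf[idx, , drop = FALSE], yf[idx], family = fam,
                          start = warm)
      if (!r$converged) stop("glm.fit did not converge")
      r$coefficients
    }
  }
  n_fail <- 0L
  for (b in seq_len(B)) {
    idx <- idx_draw()
    cfb <- if (!is.null(refit)) {
      tryCatch(suppressWarnings(refit(idx)), error = function(e) NULL)
    } else {
      db <- data[idx, , drop = FALSE]
      fit <- tryCatch(suppressWarnings(
        if (is.null(warm)) fitter(formula, db)
        else fitter(formula, db, start = warm)),
        error = function(e) NULL)
      if (is.null(fit) && !is.null(warm)) {  # cold-start fallback
        fit <- tryCatch(suppressWarnings(fitter(formula, db)),
                        error = function(e) NULL)
      }
      if (is.null(fit)) NULL else stats::coef(fit)
    }
    if (!is.null(cfb) && length(cfb) == length(cf0) && !anyNA(cfb)) {
      reps[b, ] <- cfb
    } else n_fail <- n_fail + 1L
  }
  if (n_fail > max_fail_frac * B) {
    stop("bootstrap: ", n_fail, " of ", B, " replicate fits failed ",
         "(limit ", round(max_fail_frac * B), "); model too unstable ",
         "for these data")
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  list(estimate = colMeans(reps), vcov = stats::cov(reps),
       replicates = reps, n_fail = n_fail, full_fit = full)
}

#' Combine estimates across imputed datasets with Rubin's rules
#'
#' Given per-dataset estimates \eqn{\hat Q_d} and variances \eqn{U_d}
#' (here: bootstrap means and variances), computes per coefficient the
#' pooled estimate \eqn{\bar Q = m^{-1}\sum \hat Q_d}, the within-imputation
#' variance \eqn{W = m^{-1}\sum U_d}, the between-imputation variance
#' \eqn{B = (m-1)^{-1}\sum(\hat Q_d - \bar Q)^2}, the total variance
#' \eqn{T = W + (1 + 1/m) B}, and the fraction of variance attributable to
#' missingness \eqn{\lambda = (1 + 1/m) B / T}. Confidence intervals use a
#' t reference with Barnard-Rubin adjusted degrees of freedom (reducing to
#' the complete-data df when \eqn{B = 0}).
#'
#' @param estimates m-vector (one coefficient) or m x p matrix of
#'   per-dataset estimates.
#' @param variances m-vector or m x p matrix of per-dataset variances
#'   (all non-negative).
#' @param conf_level confidence level (default 0.95).
#' @param df_com complete-data degrees of freedom for the Barnard-Rubin
#'   adjustment; `Inf` (default) gives the large-sample limit.
#' @return data frame of class `qn_pooled` with columns `term, estimate,
#'   ll, ul, W, B, T, lambda, df`.
#' @export
rubin_pool <- function(estimates, variances, conf_level = 0.95,
                       df_com = Inf) {
  if (is.vector(estimates)) estimates <- matrix(estimates, ncol = 1)
  if (is.vector(variances)) variances <- matrix(variances, ncol = 1)
  stopifnot(all(dim(estimates) == dim(variances)))
  m <- nrow(estimates)
  if (m < 2) stop("rubin_pool: need m >= 2 imputed datasets")
  if (any(variances < 0, na.rm = TRUE)) {
    stop("rubin_pool: negative variance supplied")
  }
  terms <- colnames(estimates)
  if (is.null(terms)) terms <- paste0("coef", seq_len(ncol(estimates)))
  qbar <- colMeans(estimates)
  W <- colMeans(variances)
  B <- apply(estimates, 2, stats::var)
  Tt <- W + (1 + 1 / m) * B
  lambda <- ifelse(Tt > 0, (1 + 1 / m) * B / Tt, 0)
  df <- vapply(seq_along(qbar), function(j) {
    .barnard_rubin(m, lambda[j], df_com)
  }, numeric(1))
  alpha <- 1 - conf_level
  tcrit <- stats::qt(1 - alpha / 2, df)
  out <- data.frame(term = terms, estimate = qbar,
                    ll = qbar - tcrit * sqrt(Tt),
                    ul = qbar + tcrit * sqrt(Tt),
                    W = W, B = B, T = Tt, lambda = lambda, df = df,
                    row.names = NULL)
  class(out) <- c("qn_pooled", "data.frame")
  out
}

.barnard_rubin <- function(m, lambda, df_com) {
  if (lambda <= 0) return(if (is.finite(df_com)) df_com else Inf)
  df_old <- (m - 1) / lambda^2
  if (!is.finite(df_com)) return(df_old)
  df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lambda)
  df_old * df_obs / (df_old + df_obs)
}

#' @export
print.qn_pooled <- function(x, digits = 4, ...) {
  cat("Rubin-pooled estimates (", nrow(x), " terms )\n", sep = "")
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Bootstrap-then-pool across an imputed stack
#'
#' Runs [bootstrap_coefficients()] on each of the `m` imputed datasets
#' (independent resampling seeds derived from `seed`) and combines the
#' per-dataset means and variances with [rubin_pool()] — the full
#' "fit 500 x m models" pooling procedure in one call.
#'
#' @param stacks `qn_imputed` object or list of completed data frames.
#' @param formula final model formula.
#' @param fitter fitter function.
#' @param B replicates per dataset (default 500).
#' @param seed base seed; dataset d resamples with `seed + d`.
#' @param ... passed to [bootstrap_coefficients()].
#' @return a `qn_pooled` data frame; the per-dataset bootstrap summaries
#'   are attached as attribute `"ensembles"`.
#' @export
pool_bootstrap <- function(stacks, formula, fitter = fitter_beta(),
                           B = 500L, seed = 1L, ...) {
  datasets <- if (inherits(stacks, "qn_imputed")) stacks$datasets
              else if (is.data.frame(stacks)) list(stacks) else stacks
  ens <- lapply(seq_along(datasets), function(d) {
    bootstrap_coefficients(datasets[[d]], formula, fitter, B = B,
                           seed = seed + d, ...)
  })
  est <- do.call(rbind, lapply(ens, `[[`, "estimate"))
  vars <- do.call(rbind, lapply(ens, function(e) diag(e$vcov)))
  pooled <- rubin_pool(est, vars)
  attr(pooled, "ensembles") <- ens
  pooled
}
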