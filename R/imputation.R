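#' Build an imputation plan for a cohort table
#'
#' Chooses a conditional model per variable with missing cells: predictive
#' mean matching (PMM) for continuous variables, ridge-stabilized logistic
#' regression for binary factors, polytomous (multinomial) regression for
#' factors with more than two observed levels, and optionally a
#' classification/regression tree (`"cart"`). Subgroup-restricted factors
#' carry the explicit level `"irrelevant"` outside their subgroup and are
#' only ever imputed (and modelled) within it; subgroup-restricted
#' continuous variables listed in `restricted` are imputed, then blanked
#' outside their subgroup by post-processing, and are never used as
#' predictors for other variables.
#'
#' @param data the cohort with missing cells.
#' @param methods optional named character vector overriding the automatic
#'   method choice (`"pmm"`, `"logreg"`, `"polyreg"`, `"cart"`).
#' @param m number of imputed datasets (default 5).
#' @param burn_in iterations of the fully-conditional cycle per chain
#'   (default 5).
#' @param donor_k PMM donor pool size (default 5).
#' @param predictors columns used as predictors; defaults to every column
#'   except `id`, the restricted continuous variables, and the EQ-5D
#'   dimension columns.
#' @param restricted named list mapping a continuous variable name to a
#'   one-sided formula of the rows where it is defined, e.g.
#'   `list(n_grandchildren = ~ group == "elderly")`.
#' @param seed base RNG seed; chain k uses `seed + k`.
#' @return object of class `qn_imputation_plan`.
#' @export
imputation_plan <- function(data, methods = NULL, m = 5L, burn_in = 5L,
                            donor_k = 5L, predictors = NULL,
                            restricted = list(n_grandchildren =
                                                ~ group == "elderly"),
                            seed = 1L) {
  stopifnot(m >= 2, burn_in >= 1, donor_k >= 1)
  restricted <- restricted[names(restricted) %in% names(data)]
  miss <- vapply(data, function(x) anyNA(x), logical(1))
  # by-design blanks of restricted variables are not "missing"
  for (v in names(restricted)) {
    keep <- eval(restricted[[v]][[2]], data)
    miss[v] <- anyNA(data[[v]][keep])
  }
  targets <- names(data)[miss]
  auto <- vapply(targets, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) return("pmm")
    lev <- setdiff(levels(droplevels(factor(x[!is.na(x)]))), "irrelevant")
    if (length(lev) <= 2L) "logreg" else "polyreg"
  }, character(1))
  if (!is.null(methods)) {
    bad <- setdiff(names(methods), names(data))
    if (length(bad)) stop("method for unknown variable(s): ",
                          paste(bad, collapse = ", "))
    auto[intersect(names(methods), targets)] <-
      methods[intersect(names(methods), targets)]
  }
  if (is.null(predictors)) {
    predictors <- setdiff(names(data),
                          c("id", names(restricted),
                            c("mobility", "selfcare", "usual", "pain",
                              "anxiety")))
  }
  structure(list(methods = auto, targets = targets, m = as.integer(m),
                 burn_in = as.integer(burn_in), donor_k = as.integer(donor_k),
                 predictors = predictors, restricted = restricted,
                 seed = seed),
            class = "qn_imputation_plan")
}

#' @export
print.qn_imputation_plan <- function(x, ...) {
  cat("FCS imputation plan: m =", x$m, ", burn-in =", x$burn_in,
      ", PMM donors =", x$donor_k, "\n")
  if (length(x$methods)) {
    cat("Per-variable methods:\n")
    print(x$methods)
  } else cat("No variables need imputation.\n")
  invisible(x)
}

#' Predictive-mean-matching draw
#'
#' For each missing case, the donor pool is the `donor_k` observed cases
#' whose predicted means are closest to the missing case's predicted mean;
#' one donor is chosen uniformly at random and its *observed* value is
#' imputed, so imputations always lie in the observed support.
#'
#' @param y_obs observed values of the target variable.
#' @param pred_obs predicted means for the observed cases.
#' @param pred_mis predicted means for the missing cases.
#' @param donor_k donor pool size; reduced with a warning if fewer donors
#'   exist.
#' @return imputed values, one per element of `pred_mis`.
#' @export
pmm_draw <- function(y_obs, pred_obs, pred_mis, donor_k = 5L) {
  stopifnot(length(y_obs) == length(pred_obs))
  if (length(y_obs) < donor_k) {
    warning("fewer observed donors (", length(y_obs), ") than donor_k (",
            donor_k, "); reducing pool")
    donor_k <- length(y_obs)
  }
  vapply(pred_mis, function(p) {
    d <- abs(pred_obs - p)
    pool <- order(d)[seq_len(donor_k)]
    y_obs[pool[sample.int(donor_k, 1L)]]
  }, y_obs[1])
}

## Ridge-stabilized logistic IRLS; returns coefficients and vcov. The ridge
## keeps estimates finite under (quasi-)separation, the failure mode that
## otherwise breaks logistic imputation in small subgroups.
.ridge_logit <- function(X, y, lambda = 1e-4, maxit = 50L) {
  p <- ncol(X)
  beta <- rep(0, p)
  pen <- diag(lambda, p); pen[1, 1] <- 0  # never penalize the intercept
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    H <- XtW %*% X + pen
    beta_new <- tryCatch(solve(H, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) {  # raise the ridge and restart
      return(.ridge_logit(X, y, lambda = max(lambda * 100, 1), maxit = maxit))
    }
    beta_new <- drop(beta_new)
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  if (max(abs(beta)) > 15) {
    # separation: stabilize harder rather than report huge estimates
    return(.ridge_logit(X, y, lambda = max(lambda * 1000, 0.5),
                        maxit = maxit))
  }
  eta <- drop(X %*% beta)
  w <- pmax(stats::plogis(eta) * (1 - stats::plogis(eta)), 1e-10)
  V <- tryCatch(solve(t(X * w) %*% X + pen),
                error = function(e) diag(1e-6, p))
  list(coef = beta, vcov = V)
}

## Draw from the approximate posterior of a normal linear model, then match.
.impute_pmm <- function(y_obs, X_obs, X_mis, donor_k) {
  qrx <- qr(X_obs)
  keep <- qrx$pivot[seq_len(qrx$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]; X_mis <- X_mis[, keep, drop = FALSE]
  fit <- stats::lm.fit(X_obs, y_obs)
  beta <- fit$coefficients
  df <- max(length(y_obs) - length(beta), 1L)
  s2 <- sum(fit$residuals^2) / stats::rchisq(1, df)
  XtX <- crossprod(X_obs) + diag(1e-8, ncol(X_obs))
  R <- chol(solve(XtX))
  beta_star <- beta + sqrt(s2) * drop(t(R) %*% stats::rnorm(length(beta)))
  pmm_draw(y_obs, drop(X_obs %*% beta), drop(X_mis %*% beta_star), donor_k)
}

.impute_logreg <- function(y_obs, X_obs, X_mis, levels2) {
  fit <- .ridge_logit(X_obs, as.numeric(y_obs == levels2[2]))
  R <- tryCatch(chol(fit$vcov), error = function(e) diag(0, length(fit$coef)))
  beta_star <- fit$coef + drop(t(R) %*% stats::rnorm(length(fit$coef)))
  p <- stats::plogis(drop(X_mis %*% beta_star))
  levels2[1L + (stats::runif(nrow(X_mis)) < p)]
}

.impute_polyreg <- function(y_obs, df_obs, df_mis) {
  fit <- nnet::multinom(y ~ ., data = cbind(y = y_obs, df_obs),
                        trace = FALSE, maxit = 200, MaxNWts = 5000)
  pr <- stats::predict(fit, newdata = df_mis, type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # 2-level edge case
  lev <- fit$lev
  apply(pr, 1, function(p) sample(lev, 1L, prob = p))
}

.impute_cart <- function(y_obs, df_obs, df_mis) {
  fit <- rpart::rpart(y ~ ., data = cbind(y = y_obs, df_obs),
                      method = if (is.numeric(y_obs)) "anova" else "class",
                      control = rpart::rpart.control(cp = 1e-4, minbucket = 5))
  leaf_obs <- fit$where
  # assign missing cases to leaves, then draw a donor from the same leaf
  pred_mis <- stats::predict(fit, newdata = df_mis,
                             type = if (is.numeric(y_obs)) "vector"
                             else "class")
  if (is.numeric(y_obs)) {
    pred_obs <- stats::predict(fit)
    vapply(pred_mis, function(p) {
      pool <- which(abs(pred_obs - p) < 1e-9)
      if (!length(pool)) pool <- order(abs(pred_obs - p))[1:5]
      y_obs[pool[sample.int(length(pool), 1L)]]
    }, numeric(1))
  } else {
    as.character(pred_mis)
  }
}

## Model matrix of the predictor set, excluding the target, with collinear
## columns dropped; returns also the names of dropped columns.
.predictor_matrix <- function(data, predictors, target) {
  vars <- setdiff(predictors, target)
  df <- droplevels(data[vars])
  # drop structurally uninformative columns (single-level factors appear
  # e.g. after the child-excluded sensitivity subset)
  keep <- vapply(df, function(col) {
    if (is.factor(col)) nlevels(col) >= 2L else TRUE
  }, logical(1))
  df <- df[keep]
  X <- stats::model.matrix(~ ., data = df)
  qrx <- qr(X)
  dropped <- character(0)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
  }
  list(X = X, dropped = dropped, df = df)
}

#' Impute missing values by fully conditional specification
#'
#' Runs `m` independent chains of the FCS cycle: each variable with missing
#' cells is regressed on all other (allowed) predictors given their current
#' completed values, and its missing cells are redrawn; variables are
#' visited in order of ascending missingness, for `burn_in` iterations.
#' Observed cells are never changed and are identical across the `m`
#' completed datasets. Subgroup-restricted factors are only imputed within
#' their subgroup (their `"irrelevant"` level is by design, not missing);
#' restricted continuous variables are imputed, then blanked outside their
#' subgroup.
#'
#' @param data cohort with missing cells.
#' @param plan an [imputation_plan()]; built automatically if omitted.
#' @return object of class `qn_imputed`: list with `datasets` (list of `m`
#'   completed data frames), `trace` (per-chain, per-iteration means of the
#'   imputed cells), `plan`, and `dropped` (collinear predictor columns
#'   dropped, if any).
#' @export
impute_fcs <- function(data, plan = imputation_plan(data)) {
  stopifnot(inherits(plan, "qn_imputation_plan"))
  targets <- plan$targets
  if (!length(targets)) {
    return(structure(list(datasets = replicate(plan$m, data, simplify = FALSE),
                          trace = NULL, plan = plan, dropped = character(0)),
                     class = "qn_imputed"))
  }
  # eligibility: which rows of each target can legitimately hold a value
  eligible <- lapply(targets, function(v) {
    if (v %in% names(plan$restricted)) {
      eval(plan$restricted[[v]][[2]], data)
    } else if (is.factor(data[[v]]) && "irrelevant" %in% levels(data[[v]])) {
      # subgroup factor: "irrelevant" cells are by design, not missing
      is.na(data[[v]]) | data[[v]] != "irrelevant"
    } else rep(TRUE, nrow(data))
  })
  names(eligible) <- targets
  mis_idx <- lapply(targets, function(v) which(is.na(data[[v]]) &
                                                 eligible[[v]]))
  names(mis_idx) <- targets
  visit <- targets[order(vapply(mis_idx, length, integer(1)))]

  n_iter <- plan$burn_in
  trace <- array(NA_real_, dim = c(plan$m, n_iter, length(targets)),
                 dimnames = list(NULL, NULL, targets))
  dropped_all <- character(0)
  datasets <- vector("list", plan$m)

  for (k in seq_len(plan$m)) {
    set.seed(plan$seed + k)
    cur <- data
    # initialize by sampling observed values
    for (v in targets) {
      obs_v <- cur[[v]][!is.na(cur[[v]])]
      if (is.factor(cur[[v]])) obs_v <- obs_v[obs_v != "irrelevant"]
      idx <- mis_idx[[v]]
      if (length(idx)) {
        cur[[v]][idx] <- sample(obs_v, length(idx), replace = TRUE)
      }
    }
    for (it in seq_len(n_iter)) {
      for (v in visit) {
        idx <- mis_idx[[v]]
        if (!length(idx)) next
        elig <- which(eligible[[v]])
        obs <- setdiff(elig, idx)
        y_obs <- cur[[v]][obs]
        if (is.factor(cur[[v]])) y_obs <- droplevels(y_obs)
        uy <- unique(y_obs)
        if (length(uy) == 1L) {
          if (it == 1L && k == 1L) {
            warning("variable '", v, "' has constant observed values; ",
                    "imputing the constant")
          }
          cur[[v]][idx] <- uy
          next
        }
        method <- plan$methods[[v]]
        pm <- .predictor_matrix(cur, plan$predictors, v)
        dropped_all <- union(dropped_all, pm$dropped)
        X_obs <- pm$X[obs, , drop = FALSE]
        X_mis <- pm$X[idx, , drop = FALSE]
        imp <- switch(
          method,
          pmm = .impute_pmm(y_obs, X_obs, X_mis, plan$donor_k),
          logreg = .impute_logreg(y_obs, X_obs, X_mis, levels(y_obs)),
          polyreg = .impute_polyreg(y_obs, pm$df[obs, , drop = FALSE],
                                    pm$df[idx, , drop = FALSE]),
          cart = .impute_cart(y_obs, pm$df[obs, , drop = FALSE],
                              pm$df[idx, , drop = FALSE]),
          stop("unknown imputation method '", method, "'"))
        cur[[v]][idx] <- imp
      }
      for (v in targets) {
        cell <- cur[[v]][mis_idx[[v]]]
        trace[k, it, v] <- if (length(cell) == 0L) NA_real_
        else if (is.numeric(cell)) mean(cell) else mean(as.integer(cell))
      }
    }
    # post-processing: blank restricted continuous variables off-subgroup
    for (v in names(plan$restricted)) {
      if (v %in% names(cur)) {
        keep <- eval(plan$restricted[[v]][[2]], cur)
        cur[[v]][!keep] <- NA
      }
    }
    datasets[[k]] <- cur
  }
  if (length(dropped_all)) {
    warning("collinear predictor columns dropped during imputation: ",
            paste(dropped_all, collapse = ", "))
  }
  structure(list(datasets = datasets, trace = trace, plan = plan,
                 dropped = dropped_all),
            class = "qn_imputed")
}

#' @export
print.qn_imputed <- function(x, ...) {
  cat("FCS-imputed stack: m =", length(x$datasets), "datasets,",
      length(x$plan$targets), "variables imputed over", x$plan$burn_in,
      "iterations\n")
  invisible(x)
}

#' Check FCS chains for residual drift
#'
#' Compares each chain's imputed-cell means between the first and second
#' half of the iterations. A variable is flagged when all chains drift in
#' the same direction and the mean drift is large relative to its
#' between-chain spread (one-sample t statistic above the 1% critical
#' value), the signature of a chain still trending rather than mixing.
#'
#' @param imputed a `qn_imputed` object (or its `trace` array).
#' @return data frame with one row per imputed variable: mean drift,
#'   t statistic and a logical `flagged`.
#' @export
check_convergence <- function(imputed) {
  trace <- if (inherits(imputed, "qn_imputed")) imputed$trace else imputed
  if (is.null(trace)) {
    return(data.frame(variable = character(0), drift = numeric(0),
                      t = numeric(0), flagged = logical(0)))
  }
  stopifnot(length(dim(trace)) == 3L, dim(trace)[2] >= 2L)
  n_iter <- dim(trace)[2]
  first <- seq_len(floor(n_iter / 2))
  last <- (floor(n_iter / 2) + 1L):n_iter
  vars <- dimnames(trace)[[3]]
  out <- lapply(vars, function(v) {
    drifts <- apply(trace[, , v, drop = FALSE], 1, function(ch) {
      mean(ch[last], na.rm = TRUE) - mean(ch[first], na.rm = TRUE)
    })
    drifts <- drifts[is.finite(drifts)]
    if (!length(drifts) || all(drifts == 0)) {
      return(data.frame(variable = v, drift = 0, t = 0, flagged = FALSE))
    }
    s <- stats::sd(drifts)
    tval <- if (length(drifts) < 2L || s == 0) {
      if (mean(drifts) != 0) Inf else 0
    } else mean(drifts) / (s / sqrt(length(drifts)))
    same_sign <- all(drifts >= 0) || all(drifts <= 0)
    crit <- if (length(drifts) >= 2L)
      stats::qt(0.995, df = length(drifts) - 1L) else Inf
    data.frame(variable = v, drift = mean(drifts), t = tval,
               flagged = same_sign && abs(tval) > crit)
  })
  do.call(rbind, out)
}
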