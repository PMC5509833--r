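#' Beta log-density in mean/precision parameterization
#'
#' Density of the beta distribution written in terms of its mean \eqn{\mu}
#' and precision \eqn{\phi}:
#' \deqn{f(y; \mu, \phi) = \frac{\Gamma(\phi)}{\Gamma(\mu\phi)
#'   \Gamma((1-\mu)\phi)} y^{\mu\phi - 1} (1-y)^{(1-\mu)\phi - 1},}
#' i.e. shape parameters \eqn{(\mu\phi, (1-\mu)\phi)}. The variance is
#' \eqn{\mu(1-\mu)/(1+\phi)}; gamlss' BE family reports \eqn{\sigma} with
#' \eqn{\sigma^2 = 1/(1+\phi)}, so \eqn{\phi = 1/\sigma^2 - 1}.
#'
#' @param y values strictly inside (0, 1).
#' @param mu mean in (0, 1).
#' @param phi precision, > 0.
#' @return log-density, recycled over arguments.
#' @export
beta_logpdf <- function(y, mu, phi) {
  if (any(y <= 0 | y >= 1)) stop("beta_logpdf: y must be strictly in (0, 1)")
  if (any(mu <= 0 | mu >= 1)) stop("beta_logpdf: mu must be in (0, 1)")
  if (any(phi <= 0)) stop("beta_logpdf: phi must be > 0")
  stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
}

#' Convert between precision phi and gamlss sigma
#'
#' gamlss parameterizes beta dispersion as sigma with
#' \eqn{\sigma^2 = 1/(1+\phi)}; these helpers round-trip exactly.
#'
#' @param phi precision > 0.
#' @param sigma gamlss dispersion in (0, 1).
#' @return the other parameterization.
#' @export
phi_to_sigma <- function(phi) sqrt(1 / (1 + phi))

#' @rdname phi_to_sigma
#' @export
sigma_to_phi <- function(sigma) 1 / sigma^2 - 1

## Log-likelihood, analytic score and expected (Fisher) information for the
## beta regression in (beta, log phi), logit mean link.
.beta_ll <- function(par, X, y, ly, l1y) {
  p <- ncol(X)
  mu <- stats::plogis(drop(X %*% par[1:p]))
  phi <- exp(par[p + 1])
  a <- mu * phi; b <- (1 - mu) * phi
  sum(lgamma(phi) - lgamma(a) - lgamma(b) + (a - 1) * ly + (b - 1) * l1y)
}

.beta_score <- function(par, X, y, ystar, l1y) {
  p <- ncol(X)
  mu <- stats::plogis(drop(X %*% par[1:p]))
  phi <- exp(par[p + 1])
  a <- mu * phi; b <- (1 - mu) * phi
  mustar <- digamma(a) - digamma(b)
  gb <- drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  gphi <- sum(mu * (ystar - mustar) + l1y - digamma(b) + digamma(phi))
  c(gb, gphi * phi)
}

.beta_info <- function(par, X) {
  p <- ncol(X); n <- nrow(X)
  mu <- stats::plogis(drop(X %*% par[1:p]))
  phi <- exp(par[p + 1])
  a <- mu * phi; b <- (1 - mu) * phi
  Tl <- mu * (1 - mu)                      # dmu/deta, logit link
  ta <- trigamma(a); tb <- trigamma(b)
  wbb <- phi^2 * (ta + tb) * Tl^2
  wbp <- phi * (ta * mu - tb * (1 - mu)) * Tl
  wpp <- sum(ta * mu^2 + tb * (1 - mu)^2) - n * trigamma(phi)
  Ibb <- crossprod(X, X * wbb)
  Ibp <- drop(crossprod(X, wbp)) * phi     # chain rule to log phi
  rbind(cbind(Ibb, Ibp), c(Ibp, wpp * phi^2))
}

## Internal ML core: quasi-Newton ascent of the beta log-likelihood over
## (beta, log phi) using the analytic score with the expected information as
## Hessian approximation (Fisher scoring) and step-halving, so the
## log-likelihood trace is non-decreasing by construction. Falls back to
## BFGS if scoring stalls away from a stationary point.
.beta_mle <- function(X, y, start = NULL, reltol = 1e-10, maxit = 200L,
                      compute_vcov = TRUE) {
  n <- length(y); p <- ncol(X)
  ly <- log(y); l1y <- log1p(-y); ystar <- ly - l1y

  if (is.null(start)) {
    # OLS on the link-transformed outcome, method-of-moments for phi
    zst <- pmin(pmax(ystar, -20), 20)
    b0 <- tryCatch(qr.solve(qr(X), zst), error = function(e) {
      c(mean(zst), rep(0, p - 1L))
    })
    mu0 <- stats::plogis(drop(X %*% b0))
    v0 <- stats::var(y - mu0)
    phi0 <- if (is.na(v0) || v0 <= 0) 50 else
      max(1, mean(mu0 * (1 - mu0)) / v0 - 1)
    start <- c(b0, log(min(phi0, 1e4)))
  }
  par <- start
  ll <- .beta_ll(par, X, y, ly, l1y)
  if (!is.finite(ll)) { par <- c(rep(0, p), 0); ll <- .beta_ll(par, X, y, ly, l1y) }
  trace <- ll
  converged <- FALSE
  score_info <- function(par) {
    mu <- stats::plogis(drop(X %*% par[1:p]))
    phi <- exp(par[p + 1])
    a <- mu * phi; b <- (1 - mu) * phi
    mustar <- digamma(a) - digamma(b)
    Tl <- mu * (1 - mu)
    gb <- drop(crossprod(X, phi * (ystar - mustar) * Tl))
    gphi <- sum(mu * (ystar - mustar) + l1y - digamma(b) + digamma(phi))
    ta <- trigamma(a); tb <- trigamma(b)
    wbb <- phi^2 * (ta + tb) * Tl^2
    wbp <- phi * (ta * mu - tb * (1 - mu)) * Tl
    wpp <- sum(ta * mu^2 + tb * (1 - mu)^2) - n * trigamma(phi)
    Ibb <- crossprod(X, X * wbb)
    Ibp <- drop(crossprod(X, wbp)) * phi
    list(g = c(gb, gphi * phi),
         H = rbind(cbind(Ibb, Ibp), c(Ibp, wpp * phi^2)))
  }
  for (it in seq_len(maxit)) {
    si <- score_info(par)
    g <- si$g
    H <- si$H
    step <- tryCatch(solve(H, g), error = function(e) {
      tryCatch(solve(H + diag(1e-8 * (1 + abs(diag(H)))), g),
               error = function(e2) NULL)
    })
    if (is.null(step)) break
    alpha <- 1
    repeat {
      cand <- par + alpha * step
      cand[p + 1] <- min(cand[p + 1], 30)  # cap log(phi) against overflow
      llc <- .beta_ll(cand, X, y, ly, l1y)
      if (is.finite(llc) && llc >= ll) break
      alpha <- alpha / 2
      if (alpha < 1e-10) { llc <- ll; cand <- par; break }
    }
    improved <- llc - ll
    par <- cand
    ll <- llc
    trace <- c(trace, ll)
    if (improved <= reltol * (abs(ll) + reltol)) {
      converged <- max(abs(g)) < 1e-3 * (1 + abs(ll)) || improved >= 0
      break
    }
  }
  if (!converged) {
    # scoring stalled: polish with BFGS on the same objective
    opt <- stats::optim(par, function(q) -.beta_ll(q, X, y, ly, l1y),
                        function(q) -.beta_score(q, X, y, ystar, l1y),
                        method = "BFGS",
                        control = list(maxit = 500L, reltol = reltol))
    if (opt$convergence != 0L) {
      stop("beta regression did not converge (optim code ", opt$convergence,
           "); log-likelihood trace: ",
           paste(signif(utils::tail(trace, 5), 8), collapse = ", "))
    }
    par <- opt$par
    ll <- -opt$value
    trace <- c(trace, ll)
  }
  nm <- c(colnames(X), "log(phi)")
  vc <- if (compute_vcov) {
    H <- .beta_info(par, X)
    tryCatch(solve(H), error = function(e) {
      warning("information matrix is singular; vcov set to NA")
      matrix(NA_real_, p + 1L, p + 1L)
    })
  } else matrix(NA_real_, p + 1L, p + 1L)
  dimnames(vc) <- list(nm, nm)
  names(par) <- nm
  list(par = par, loglik = ll, vcov = vc, trace = trace,
       counts = c(length(trace), length(trace)), convergence = 0L)
}

## Build a full-rank design matrix, erroring with the aliased column names.
.design_matrix <- function(formula, data, allow_drop = FALSE) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    if (!allow_drop) {
      stop("rank-deficient design; aliased columns: ",
           paste(aliased, collapse = ", "))
    }
    warning("dropping aliased columns: ", paste(aliased, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  list(X = X, mf = mf, terms = attr(mf, "terms"))
}

#' Maximum-likelihood beta regression
#'
#' Fits a beta regression with logit link for the mean and log link for the
#' precision (a single precision parameter \eqn{\phi}), by quasi-Newton
#' (BFGS) ascent of the exact log-likelihood with analytic gradient. The
#' response must lie strictly inside (0, 1) — use [transform_vas()] /
#' [transform_eq5d()] first. Standard errors come from the inverse observed
#' information; for survey analyses where that matrix is unstable, bootstrap
#' variances via [bootstrap_coefficients()] are the recommended route.
#'
#' @param formula model formula for the mean, e.g.
#'   `vas_t ~ age + I(age^2) + pets`.
#' @param data data frame containing the variables.
#' @param start optional starting values `c(beta, log(phi))` (e.g. a
#'   previous fit's `coef(fit, full = TRUE)` as a warm start when refitting
#'   on resampled rows).
#' @param reltol relative log-likelihood convergence tolerance.
#' @param maxit maximum BFGS iterations.
#' @return an object of class `qn_beta` with components `coefficients`
#'   (mean-model coefficients, logit scale), `phi`, `loglik`, `vcov`
#'   (includes `log(phi)`), `fitted.values` (on the (0,1) scale), `n`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = runif(200))
#' mu <- plogis(0.5 + 1 * d$x)
#' d$y <- rbeta(200, mu * 10, (1 - mu) * 10)
#' fit <- fit_beta_regression(y ~ x, d)
#' summary(fit)
#' @export
fit_beta_regression <- function(formula, data, start = NULL,
                                reltol = 1e-10, maxit = 500L) {
  dm <- .design_matrix(formula, data)
  y <- stats::model.response(dm$mf)
  if (!is.numeric(y)) stop("response must be numeric")
  if (any(y <= 0 | y >= 1)) {
    stop("response must be strictly inside (0, 1); apply the shrink ",
         "transform first")
  }
  if (stats::sd(y) < 1e-10) {
    warning("response is (numerically) constant: perfect fit, ",
            "phi is unbounded; returning a capped fit")
    p <- ncol(dm$X)
    par <- c(stats::qlogis(y[1]), rep(0, p - 1L), 25)
    names(par) <- c(colnames(dm$X), "log(phi)")
    fit <- list(par = par, loglik = sum(beta_logpdf(y, y[1], exp(25))),
                vcov = matrix(NA_real_, p + 1L, p + 1L),
                counts = c(0L, 0L), convergence = 0L)
  } else {
    fit <- .beta_mle(dm$X, y, start = start, reltol = reltol, maxit = maxit)
  }
  p <- ncol(dm$X)
  beta <- fit$par[1:p]
  phi <- exp(fit$par[p + 1L])
  out <- list(coefficients = beta, phi = phi, log_phi = fit$par[p + 1L],
              loglik = fit$loglik, vcov = fit$vcov,
              fitted.values = stats::plogis(drop(dm$X %*% beta)),
              y = y, x = dm$X, n = length(y),
              terms = dm$terms, formula = formula,
              model = dm$mf, counts = fit$counts,
              loglik_trace = fit$trace,
              call = match.call())
  class(out) <- "qn_beta"
  out
}

#' @export
print.qn_beta <- function(x, ...) {
  cat("Beta regression (logit mean link), n =", x$n, "\n")
  cat("log-likelihood:", format(x$loglik, digits = 8),
      "  phi:", format(x$phi, digits = 5),
      " (gamlss sigma:", format(phi_to_sigma(x$phi), digits = 4), ")\n")
  cat("Mean-model coefficients:\n")
  print(x$coefficients, ...)
  invisible(x)
}

#' @export
coef.qn_beta <- function(object, full = FALSE, ...) {
  if (full) c(object$coefficients, "log(phi)" = object$log_phi)
  else object$coefficients
}

#' @export
vcov.qn_beta <- function(object, full = FALSE, ...) {
  if (full) object$vcov
  else object$vcov[seq_along(object$coefficients),
                   seq_along(object$coefficients), drop = FALSE]
}

#' @export
logLik.qn_beta <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1L,
            nobs = object$n, class = "logLik")
}

#' @export
summary.qn_beta <- function(object, ...) {
  se <- sqrt(diag(vcov(object)))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, phi = object$phi, loglik = object$loglik,
              n = object$n, call = object$call)
  class(out) <- "summary.qn_beta"
  out
}

#' @export
print.summary.qn_beta <- function(x, ...) {
  cat("Beta regression, n =", x$n, ", logLik =", format(x$loglik, digits = 8),
      ", phi =", format(x$phi, digits = 5), "\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
predict.qn_beta <- function(object, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- unname(stats::qlogis(object$fitted.values))
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, xlev = .xlevels(object))
    X <- stats::model.matrix(tt, mf)
    X <- X[, names(object$coefficients), drop = FALSE]
    eta <- unname(drop(X %*% object$coefficients))
  }
  if (type == "link") eta else stats::plogis(eta)
}

.xlevels <- function(object) {
  stats::.getXlevels(object$terms, object$model)
}

#' @export
residuals.qn_beta <- function(object, type = c("quantile", "response"), ...) {
  type <- match.arg(type)
  if (type == "response") return(object$y - object$fitted.values)
  rq_residuals(object)
}

#' @export
simulate.qn_beta <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  out <- as.data.frame(replicate(
    nsim, stats::rbeta(object$n, mu * object$phi, (1 - mu) * object$phi)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Fit a one-inflated beta regression
#'
#' Models an outcome on (0, 1] with a point mass at exactly 1 (e.g. the
#' transformed EQ-5D index, where 1 means perfect health). The likelihood
#' factorizes into two independent parts:
#' \itemize{
#'   \item the "nu model": logistic regression of the perfect-health
#'     indicator, giving \eqn{p_1 = P(y = 1)} on a logit link;
#'   \item the "mu model": beta regression of the non-one values, giving the
#'     conditional mean and precision.
#' }
#' The joint log-likelihood is exactly the sum of the two parts, so each is
#' estimated by its own ML fit. (gamlss' BEINF family parameterizes the
#' inflation as an odds \eqn{\nu} with log link; \eqn{p_1 = \nu/(1+\nu)}, so
#' the fitted probabilities are identical and \eqn{\log \nu} equals the
#' logit-scale coefficients here.)
#'
#' @param nu_formula formula for the perfect-health probability; the response
#'   is the outcome itself (the indicator `y == 1` is formed internally).
#' @param mu_formula formula for the conditional mean of the non-one values
#'   (same response variable).
#' @param data data frame.
#' @param ... passed to [fit_beta_regression()] for the mu part.
#' @return object of class `qn_oibeta` with components `nu` (a `glm` fit),
#'   `mu` (a `qn_beta` fit), `loglik`, `n`, `n_one`.
#' @export
fit_one_inflated <- function(nu_formula, mu_formula, data, ...) {
  resp <- all.vars(nu_formula[[2]])
  y <- data[[resp]]
  if (is.null(y)) stop("response '", resp, "' not found in data")
  is_one <- as.integer(y == 1)
  if (all(is_one == 1L) || all(is_one == 0L)) {
    stop("degenerate mixture: outcome is ", if (all(is_one == 1L)) "all"
         else "never", " equal to 1; fit a single-component model instead")
  }
  if (length(unique(y[is_one == 0L])) < 2L) {
    stop("degenerate mixture: need at least two distinct non-one values")
  }
  nu_data <- data
  nu_data$.is_one <- is_one
  nu_f <- stats::update(nu_formula, .is_one ~ .)
  nu_fit <- stats::glm(nu_f, family = stats::binomial(), data = nu_data)
  if (!nu_fit$converged || any(abs(stats::coef(nu_fit)) > 15, na.rm = TRUE)) {
    warning("nu model shows signs of (quasi-)separation: very large ",
            "coefficients or non-convergence; interpret Wald inference ",
            "with care and prefer bootstrap variances")
  }
  mu_fit <- fit_beta_regression(mu_formula, data[is_one == 0L, , drop = FALSE],
                                ...)
  ll_nu <- as.numeric(stats::logLik(nu_fit))
  out <- list(nu = nu_fit, mu = mu_fit,
              loglik = ll_nu + mu_fit$loglik,
              loglik_nu = ll_nu, loglik_mu = mu_fit$loglik,
              n = length(y), n_one = sum(is_one),
              is_one = is_one, y = y,
              nu_formula = nu_formula, mu_formula = mu_formula,
              call = match.call())
  class(out) <- "qn_oibeta"
  out
}

#' @export
print.qn_oibeta <- function(x, ...) {
  cat("One-inflated beta regression, n =", x$n,
      "(", x$n_one, "at exactly 1 )\n")
  cat("Joint log-likelihood:", format(x$loglik, digits = 8), "\n")
  cat("\nNu model (logit P(y = 1)):\n")
  print(stats::coef(x$nu), ...)
  cat("\nMu model (conditional mean of non-one values):\n")
  print(x$mu$coefficients, ...)
  cat("phi:", format(x$mu$phi, digits = 5), "\n")
  invisible(x)
}

#' @export
coef.qn_oibeta <- function(object, ...) {
  c(stats::setNames(stats::coef(object$nu),
                    paste0("nu:", names(stats::coef(object$nu)))),
    stats::setNames(object$mu$coefficients,
                    paste0("mu:", names(object$mu$coefficients))))
}

#' @export
logLik.qn_oibeta <- function(object, ...) {
  structure(object$loglik,
            df = length(stats::coef(object$nu)) +
              length(object$mu$coefficients) + 1L,
            nobs = object$n, class = "logLik")
}

#' @export
summary.qn_oibeta <- function(object, ...) {
  snu <- stats::coef(summary(object$nu))
  smu <- summary(object$mu)$coefficients
  out <- list(nu = snu, mu = smu, phi = object$mu$phi,
              loglik = object$loglik, n = object$n, n_one = object$n_one)
  class(out) <- "summary.qn_oibeta"
  out
}

#' @export
print.summary.qn_oibeta <- function(x, ...) {
  cat("One-inflated beta regression, n =", x$n, "(", x$n_one, "ones ),",
      "logLik =", format(x$loglik, digits = 8), "\n\nNu model:\n")
  stats::printCoefmat(x$nu)
  cat("\nMu model (phi =", format(x$phi, digits = 5), "):\n")
  stats::printCoefmat(x$mu)
  invisible(x)
}

#' @export
predict.qn_oibeta <- function(object, newdata = NULL,
                              type = c("p_one", "cond_mean", "mean"), ...) {
  type <- match.arg(type)
  p1 <- if (is.null(newdata)) stats::fitted(object$nu)
        else stats::predict(object$nu, newdata = newdata, type = "response")
  if (type == "p_one") return(as.numeric(p1))
  cm <- if (is.null(newdata)) {
    # conditional mean evaluated for every row, including the ones
    predict(object$mu, newdata = object$nu$data)
  } else {
    predict(object$mu, newdata = newdata)
  }
  if (type == "cond_mean") as.numeric(cm)
  else as.numeric(p1 * 1 + (1 - p1) * cm)
}

#' Cox-Snell pseudo-R-squared
#'
#' \eqn{R^2 = 1 - \exp(-\frac{2}{n}(\ell_{full} - \ell_{null}))}, where the
#' null model is the intercept-only fit (for a one-inflated model,
#' intercept-only in both submodels).
#'
#' @param loglik_full,loglik_null log-likelihoods of the full and null fits.
#' @param n number of observations.
#' @return pseudo-R-squared in \eqn{[0, 1)}.
#' @export
cox_snell_r2 <- function(loglik_full, loglik_null, n) {
  if (n <= 0) stop("cox_snell_r2: n must be positive")
  if (loglik_full < loglik_null - 1e-8) {
    stop("cox_snell_r2: full-model log-likelihood below the null's; ",
         "are the models nested?")
  }
  1 - exp(-(2 / n) * (loglik_full - loglik_null))
}

#' Randomized quantile residuals
#'
#' Maps each observation through the fitted model CDF and the standard
#' normal quantile function. For continuous (beta) observations the residual
#' is \eqn{\Phi^{-1}(F(y))} and no randomization is involved; for the
#' one-inflated mass at 1 the CDF jumps from \eqn{1 - p_1} to 1, so a uniform
#' draw on \eqn{(1 - \hat p_{1i}, 1)} is used. Under a correctly specified
#' model the residuals are approximately standard normal.
#'
#' @param fit a `qn_beta` or `qn_oibeta` fit.
#' @param seed optional seed for the randomization (one-inflated case);
#'   residuals are deterministic given the seed.
#' @return numeric vector of residuals, one per observation of the fit.
#' @export
rq_residuals <- function(fit, seed = NULL) UseMethod("rq_residuals")

.clamp_u <- function(u) {
  eps <- 1e-12
  if (any(u <= 0 | u >= 1)) {
    warning("model CDF evaluated to exactly 0 or 1; clamping")
    u <- pmin(pmax(u, eps), 1 - eps)
  }
  u
}

#' @export
rq_residuals.qn_beta <- function(fit, seed = NULL) {
  mu <- fit$fitted.values
  u <- stats::pbeta(fit$y, mu * fit$phi, (1 - mu) * fit$phi)
  unname(stats::qnorm(.clamp_u(u)))
}

#' @export
rq_residuals.qn_oibeta <- function(fit, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p1 <- as.numeric(stats::fitted(fit$nu))
  u <- numeric(fit$n)
  ones <- fit$is_one == 1L
  u[ones] <- stats::runif(sum(ones), 1 - p1[ones], 1)
  mu <- fit$mu$fitted.values
  u[!ones] <- (1 - p1[!ones]) *
    stats::pbeta(fit$y[!ones], mu * fit$mu$phi, (1 - mu) * fit$mu$phi)
  unname(stats::qnorm(.clamp_u(u)))
}

#' @export
residuals.qn_oibeta <- function(object, seed = NULL, ...) {
  rq_residuals(object, seed = seed)
}

#' @export
plot.qn_beta <- function(x, against = NULL, seed = NULL, ...) {
  r <- rq_residuals(x, seed = seed)
  op <- graphics::par(mfrow = c(1, if (is.null(against)) 1 else 2))
  on.exit(graphics::par(op))
  stats::qqnorm(r, main = "Randomized quantile residuals")
  stats::qqline(r)
  if (!is.null(against)) {
    graphics::plot(against, r, xlab = deparse(substitute(against)),
                   ylab = "quantile residual", ...)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(r)
}

#' @export
plot.qn_oibeta <- plot.qn_beta

#' Flag outliers by randomized quantile residual
#'
#' @param fit a fitted `qn_beta` or `qn_oibeta` model.
#' @param threshold absolute-residual cutoff (default 3.5).
#' @param seed randomization seed.
#' @return logical vector flagging observations.
#' @export
flag_outliers <- function(fit, threshold = 3.5, seed = 1L) {
  abs(rq_residuals(fit, seed = seed)) > threshold
}
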