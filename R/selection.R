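#' Fitters for use with selection, pooling and norm curves
#'
#' A *fitter* is a function `(formula, data, start = NULL) -> fit` where
#' the fit supports `coef()`, `vcov()` and `logLik()` (`start` is an
#' optional warm start used by bootstrap refits). Three fitters cover the
#' survey outcomes:
#' \itemize{
#'   \item `fitter_beta()` — beta regression of a (0,1) outcome (e.g.
#'     transformed VAS);
#'   \item `fitter_nu()` — logistic regression of the perfect-health
#'     indicator `outcome == 1` (the nu part of the one-inflated model);
#'   \item `fitter_mu()` — beta regression of the non-one outcome values
#'     (the mu part of the one-inflated model).
#' }
#' In each case the formula names the outcome itself; the indicator /
#' subsetting is handled internally.
#'
#' @return a fitter function.
#' @export
fitter_beta <- function() {
  function(formula, data, start = NULL) {
    fit_beta_regression(formula, data, start = start)
  }
}

#' @rdname fitter_beta
#' @export
fitter_nu <- function() {
  function(formula, data, start = NULL) {
    resp <- all.vars(formula[[2]])
    data$.is_one <- as.integer(data[[resp]] == 1)
    f <- stats::update(formula, .is_one ~ .)
    fit <- stats::glm(f, family = stats::binomial(), data = data,
                      start = start)
    if (!fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
      warning("nu model shows signs of (quasi-)separation")
    }
    fit
  }
}

#' @rdname fitter_beta
#' @export
fitter_mu <- function() {
  function(formula, data, start = NULL) {
    resp <- all.vars(formula[[2]])
    fit_beta_regression(formula, data[data[[resp]] != 1, , drop = FALSE],
                        start = start)
  }
}

## Joint Wald p-value per term (factor terms tested as a block).
.term_pvalues <- function(fit, formula) {
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  if (inherits(fit, "qn_beta")) V <- vcov(fit)  # mean part only
  tt <- stats::terms(formula)
  labels <- attr(tt, "term.labels")
  asg <- if (inherits(fit, "qn_beta")) attr(fit$x, "assign")
         else attr(stats::model.matrix(fit), "assign")
  keep <- !is.na(cf)
  cf <- cf[keep]; V <- V[keep, keep, drop = FALSE]; asg <- asg[keep]
  p <- vapply(seq_along(labels), function(i) {
    cols <- which(asg == i)
    if (!length(cols)) return(NA_real_)
    b <- cf[cols]
    W <- tryCatch(drop(t(b) %*% solve(V[cols, cols, drop = FALSE]) %*% b),
                  error = function(e) NA_real_)
    stats::pchisq(W, df = length(cols), lower.tail = FALSE)
  }, numeric(1))
  stats::setNames(p, labels)
}

#' Backward elimination across imputed datasets
#'
#' Step one of the two-step selection: the model is fitted separately on
#' each of the `m` imputed datasets and factor terms are Wald-tested as
#' blocks. A term is *removable* when it is non-significant (p > `alpha`)
#' in **all** `m` datasets (equivalently: kept as soon as it is significant
#' in at least one); among removable terms, the one whose smallest
#' across-dataset p-value is largest is dropped, one term per round, until
#' every remaining term is significant somewhere. Forced-in terms (e.g. the
#' age polynomial and subgroup indicators) are never removed. Ties are
#' broken lexicographically by term label, making the procedure fully
#' deterministic.
#'
#' @param stacks a `qn_imputed` object or a list of completed data frames.
#' @param formula initial model formula.
#' @param fitter a fitter function (see [fitter_beta()]).
#' @param forced character vector of term labels never removed.
#' @param alpha significance threshold (default 0.05).
#' @param rule `"all"` (default: remove only if non-significant in all
#'   datasets) or `"any"` (remove if non-significant in any dataset).
#' @return object of class `qn_selection`: final `formula`, `history`
#'   (one row per removal), and the final per-dataset p-value matrix.
#' @export
backward_eliminate <- function(stacks, formula, fitter = fitter_beta(),
                               forced = character(0), alpha = 0.05,
                               rule = c("all", "any")) {
  rule <- match.arg(rule)
  datasets <- if (inherits(stacks, "qn_imputed")) stacks$datasets
              else if (is.data.frame(stacks)) list(stacks) else stacks
  history <- data.frame(step = integer(0), removed = character(0),
                        criterion_p = numeric(0))
  step <- 0L
  repeat {
    labels <- attr(stats::terms(formula), "term.labels")
    if (!length(labels)) {
      warning("elimination emptied the model; returning intercept-only")
      break
    }
    pmat <- vapply(datasets, function(d) {
      .term_pvalues(fitter(formula, d), formula)
    }, numeric(length(labels)))
    if (is.null(dim(pmat))) pmat <- matrix(pmat, nrow = length(labels),
                                           dimnames = list(labels, NULL))
    removable <- setdiff(labels, forced)
    nonsig <- if (rule == "all") {
      removable[apply(pmat[removable, , drop = FALSE] > alpha, 1,
                      all, na.rm = TRUE)]
    } else {
      removable[apply(pmat[removable, , drop = FALSE] > alpha, 1,
                      any, na.rm = TRUE)]
    }
    if (!length(nonsig)) break
    crit <- apply(pmat[nonsig, , drop = FALSE], 1, min, na.rm = TRUE)
    drop_term <- sort(nonsig[crit == max(crit)])[1]  # lexicographic tie-break
    step <- step + 1L
    history <- rbind(history, data.frame(step = step, removed = drop_term,
                                         criterion_p = max(crit)))
    formula <- stats::update(
      formula, stats::as.formula(paste(". ~ . -", drop_term)))
  }
  labels <- attr(stats::terms(formula), "term.labels")
  pmat <- if (length(labels)) {
    vapply(datasets, function(d) .term_pvalues(fitter(formula, d), formula),
           numeric(length(labels)))
  } else NULL
  structure(list(formula = formula, history = history, p_values = pmat,
                 alpha = alpha, rule = rule, forced = forced),
            class = "qn_selection")
}

#' @export
print.qn_selection <- function(x, ...) {
  cat("Backward elimination (", x$rule, "-datasets rule, alpha = ",
      x$alpha, ")\n", sep = "")
  cat("Final model:", deparse(x$formula), "\n")
  if (nrow(x$history)) {
    cat("Removed, in order:",
        paste(x$history$removed, collapse = ", "), "\n")
  } else cat("No terms removed.\n")
  invisible(x)
}

#' Recode a factor by merging levels
#'
#' @param data a data frame.
#' @param factor_name name of the factor column.
#' @param mapping named character vector: `old level -> new level`; levels
#'   absent from the mapping keep their name.
#' @return the data frame with the recoded factor.
#' @export
apply_merge <- function(data, factor_name, mapping) {
  x <- data[[factor_name]]
  stopifnot(is.factor(x))
  lev <- levels(x)
  new <- ifelse(lev %in% names(mapping), mapping[lev], lev)
  levels(x) <- new
  data[[factor_name]] <- x
  data
}

#' Enumerate candidate level merges from pairwise non-significance
#'
#' Proposes merging each pair of factor levels whose coefficient difference
#' is non-significant (p > `alpha`) in every imputed dataset — the
#' statistical complement of the subject-knowledge step of recategorization.
#' The `"irrelevant"` level of subgroup factors is never merged.
#'
#' @param stacks imputed stack or list of data frames.
#' @param formula model formula containing the factor.
#' @param fitter fitter function.
#' @param factor_name the factor to examine.
#' @param alpha threshold (default 0.05).
#' @return list of mappings suitable for [recategorize_aic()].
#' @export
enumerate_merges <- function(stacks, formula, fitter, factor_name,
                             alpha = 0.05) {
  datasets <- if (inherits(stacks, "qn_imputed")) stacks$datasets else stacks
  lev <- setdiff(levels(datasets[[1]][[factor_name]]), "irrelevant")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  keep <- vapply(pairs, function(pr) {
    all(vapply(datasets, function(d) {
      fit <- fitter(formula, d)
      cf <- stats::coef(fit); V <- stats::vcov(fit)
      if (inherits(fit, "qn_beta")) V <- vcov(fit)
      nm <- paste0(factor_name, pr)
      present <- nm %in% names(cf)
      if (!any(present)) return(TRUE)
      if (all(present)) {
        d12 <- cf[nm[1]] - cf[nm[2]]
        v12 <- V[nm[1], nm[1]] + V[nm[2], nm[2]] - 2 * V[nm[1], nm[2]]
      } else {  # one of the pair is the reference level
        i <- nm[present]
        d12 <- cf[i]; v12 <- V[i, i]
      }
      2 * stats::pnorm(-abs(d12 / sqrt(v12))) > alpha
    }, logical(1)))
  }, logical(1))
  lapply(pairs[keep], function(pr) {
    stats::setNames(rep(paste(pr, collapse = "_or_"), 2), pr)
  })
}

#' AIC-guided factor recategorization across imputed datasets
#'
#' Step two of the two-step selection: each candidate level merge of a
#' many-level factor is applied to every imputed dataset, the model is
#' refitted, and the coding with the lowest mean AIC across datasets is
#' retained (the original coding competes too). The AIC of a given coding
#' is invariant to the choice of reference category — this is verified
#' numerically for the winning coding over all its reference levels.
#'
#' @param stacks imputed stack or list of data frames.
#' @param formula model formula containing the factor.
#' @param fitter fitter function.
#' @param factor_name factor to recategorize (must have >= 3 levels).
#' @param merges list of mappings (see [apply_merge()]); enumerated via
#'   [enumerate_merges()] when omitted.
#' @return list with `best` (name: `"original"` or `merge_<i>`), `mapping`
#'   (`NULL` for original), `aic` (mean AIC per candidate), and
#'   `ref_invariant` (logical).
#' @export
recategorize_aic <- function(stacks, formula, fitter, factor_name,
                             merges = NULL) {
  datasets <- if (inherits(stacks, "qn_imputed")) stacks$datasets else stacks
  if (nlevels(datasets[[1]][[factor_name]]) < 3L) {
    stop("recategorize_aic: factor must have at least 3 levels")
  }
  if (is.null(merges)) {
    merges <- enumerate_merges(stacks, formula, fitter, factor_name)
  }
  mean_aic <- function(ds) {
    mean(vapply(ds, function(d) stats::AIC(fitter(formula, d)), numeric(1)))
  }
  aics <- c(original = mean_aic(datasets))
  kept <- list(original = NULL)
  for (i in seq_along(merges)) {
    mp <- merges[[i]]
    ds2 <- lapply(datasets, function(d) {
      d2 <- apply_merge(d, factor_name, mp)
      if (any(table(d2[[factor_name]]) == 0 &
              !levels(d2[[factor_name]]) %in% "irrelevant")) return(NULL)
      d2
    })
    if (any(vapply(ds2, is.null, logical(1)))) {
      warning("merge ", i, " yields an empty level; skipped")
      next
    }
    nm <- paste0("merge_", i)
    aics[nm] <- mean_aic(ds2)
    kept[[nm]] <- mp
  }
  best <- names(aics)[which.min(aics)]
  # reference-category invariance of the winning coding
  ds_best <- if (is.null(kept[[best]])) datasets else
    lapply(datasets, apply_merge, factor_name = factor_name,
           mapping = kept[[best]])
  lev <- setdiff(levels(ds_best[[1]][[factor_name]]), "irrelevant")
  ref_aics <- vapply(lev, function(rf) {
    d1 <- ds_best[[1]]
    d1[[factor_name]] <- stats::relevel(d1[[factor_name]], ref = rf)
    stats::AIC(fitter(formula, d1))
  }, numeric(1))
  ref_invariant <- diff(range(ref_aics)) < 1e-4
  if (!ref_invariant) {
    warning("AIC of the winning coding varies with the reference category; ",
            "check for aliasing")
  }
  list(best = best, mapping = kept[[best]], aic = aics,
       ref_invariant = ref_invariant)
}
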