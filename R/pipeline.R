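#' Prepare survey outcomes for modelling
#'
#' Scores the EQ-5D index from the five dimension columns when a tariff is
#' given (rows with any missing dimension get `NA`), derives the
#' [transform_spec()] from the data (N = number of respondent rows; min/max
#' of the observed non-one index values), and returns the data with the
#' spec attached. Transformed outcome columns are added per completed
#' dataset later (after imputation) via [add_transformed_outcomes()], all
#' reusing this one spec.
#'
#' @param data respondent-level table with `vas` and either `eq5d_index` or
#'   the five dimension columns (`mobility`, `selfcare`, `usual`, `pain`,
#'   `anxiety`).
#' @param tariff optional `qn_tariff` used to score the dimensions.
#' @return the data with attribute `"spec"` (a `qn_transform_spec`).
#' @export
prepare_outcomes <- function(data, tariff = NULL) {
  dims <- c("mobility", "selfcare", "usual", "pain", "anxiety")
  if (!is.null(tariff) &&
      (!"eq5d_index" %in% names(data) || all(is.na(data$eq5d_index)))) {
    if (!all(dims %in% names(data))) {
      stop("need the five dimension columns to score the index")
    }
    pm <- as.matrix(data[dims])
    ok <- stats::complete.cases(pm)
    idx <- rep(NA_real_, nrow(data))
    idx[ok] <- score_eq5d(pm[ok, , drop = FALSE], tariff)
    data$eq5d_index <- idx
  }
  nonone <- data$eq5d_index[!is.na(data$eq5d_index) & data$eq5d_index != 1]
  spec <- if (length(nonone) >= 2L && min(nonone) < max(nonone)) {
    transform_spec(nrow(data), min(nonone), max(nonone))
  } else {
    transform_spec(nrow(data))
  }
  attr(data, "spec") <- spec
  data
}

#' @rdname prepare_outcomes
#' @param spec the `qn_transform_spec` shared by all imputed datasets.
#' @return `add_transformed_outcomes()`: the data with `vas_t` and (when an
#'   index range is available) `eq5d_t` columns.
#' @export
add_transformed_outcomes <- function(data, spec) {
  if ("vas" %in% names(data)) data$vas_t <- transform_vas(data$vas, spec)
  if ("eq5d_index" %in% names(data) && !is.na(spec$min_index)) {
    data$eq5d_t <- transform_eq5d(data$eq5d_index, spec)
  }
  data
}

#' Configuration for the end-to-end norms pipeline
#'
#' @param data respondent-level survey table (or a synthetic cohort).
#' @param tariff optional `qn_tariff` for scoring the EQ-5D index from
#'   dimensions.
#' @param include_children analyse all ages (`TRUE`) or adults and elderly
#'   only (the sensitivity branch).
#' @param m,burn_in imputation settings (defaults 5 and 5).
#' @param B bootstrap replicates per imputed dataset (default 500).
#' @param seed master seed; stage seeds are derived from it.
#' @param vas_formula,nu_formula,mu_formula model formulas on the
#'   transformed outcomes; sensible defaults cover the all-ages covariates.
#' @param select run backward elimination before pooling (default `TRUE`).
#' @param forced term labels never eliminated (default: the age polynomial).
#' @param ages age grid for the norm curves; defaults to the observed range.
#' @param out_dir optional directory to write CSV/JSON outputs into.
#' @return a `qn_pipeline_config` list.
#' @export
pipeline_config <- function(data, tariff = NULL, include_children = TRUE,
                            m = 5L, burn_in = 5L, B = 500L, seed = 1L,
                            vas_formula = vas_t ~ age + I(age^2) + gender +
                              household_size + exp_self + exp_family +
                              pets + sick,
                            nu_formula = eq5d_t ~ age + I(age^2) +
                              exp_self + exp_family + pets + sick,
                            mu_formula = eq5d_t ~ age + exp_self +
                              exp_family + household_size,
                            select = TRUE,
                            forced = c("age", "I(age^2)"),
                            ages = NULL, out_dir = NULL) {
  structure(list(data = data, tariff = tariff,
                 include_children = include_children,
                 m = as.integer(m), burn_in = as.integer(burn_in),
                 B = as.integer(B), seed = as.integer(seed),
                 vas_formula = vas_formula, nu_formula = nu_formula,
                 mu_formula = mu_formula, select = select, forced = forced,
                 ages = ages, out_dir = out_dir),
            class = "qn_pipeline_config")
}

#' Run the full population-norms pipeline
#'
#' Orchestrates every stage on one dataset: optional child exclusion,
#' EQ-5D scoring, outcome transforms, FCS multiple imputation, optional
#' backward elimination per outcome model, bootstrap + Rubin pooling of the
#' final coefficients, age-only norm curves with bootstrap bands, and
#' goodness-of-fit summaries (Cox-Snell pseudo-R-squared, outlier flags).
#' All stage seeds derive from the single master seed, so a rerun with the
#' same configuration reproduces every number exactly.
#'
#' @param cfg a [pipeline_config()].
#' @return object of class `qn_pipeline`: list with `spec`, `imputed`,
#'   `selection`, `pooled`, `norms`, `diagnostics` and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "qn_pipeline_config"))
  data <- cfg$data
  if (!cfg$include_children) {
    data <- data[data$group != "child", , drop = FALSE]
    data$group <- droplevels(data$group)
    data <- droplevels(data)
  }
  data <- prepare_outcomes(data, cfg$tariff)
  spec <- attr(data, "spec")

  plan <- imputation_plan(data, m = cfg$m, burn_in = cfg$burn_in,
                          seed = cfg$seed * 1000L)
  imputed <- impute_fcs(data, plan)
  stacks <- lapply(imputed$datasets, add_transformed_outcomes, spec = spec)

  has_eq5d <- !is.na(spec$min_index)
  selection <- list()
  formulas <- list(vas = cfg$vas_formula, nu = cfg$nu_formula,
                   mu = cfg$mu_formula)
  fitters <- list(vas = fitter_beta(), nu = fitter_nu(), mu = fitter_mu())
  parts <- if (has_eq5d) c("vas", "nu", "mu") else "vas"
  if (cfg$select) {
    for (p in parts) {
      selection[[p]] <- backward_eliminate(stacks, formulas[[p]],
                                           fitters[[p]], forced = cfg$forced)
      formulas[[p]] <- selection[[p]]$formula
    }
  }
  pooled <- lapply(parts, function(p) {
    pool_bootstrap(stacks, formulas[[p]], fitters[[p]], B = cfg$B,
                   seed = cfg$seed * 100L + match(p, parts) * 10L)
  })
  names(pooled) <- parts

  ages <- cfg$ages
  if (is.null(ages)) ages <- seq(min(data$age), max(data$age))
  norms <- list(vas = predict_norms_ci(stacks, "vas_t", spec, "beta",
                                       ages = ages, B = cfg$B,
                                       seed = cfg$seed * 10L + 1L))
  if (has_eq5d) {
    norms$eq5d <- predict_norms_ci(stacks, "eq5d_t", spec, "oneinflated",
                                   ages = ages, B = cfg$B,
                                   seed = cfg$seed * 10L + 2L)
  }

  d1 <- stacks[[1]]
  vas_fit <- fit_beta_regression(formulas$vas, d1)
  vas_null <- fit_beta_regression(vas_t ~ 1, d1)
  diagnostics <- list(
    vas = list(
      r2 = cox_snell_r2(vas_fit$loglik, vas_null$loglik, vas_fit$n),
      outliers = which(flag_outliers(vas_fit, seed = cfg$seed))))
  if (has_eq5d) {
    eq_fit <- fit_one_inflated(formulas$nu, formulas$mu, d1)
    eq_null <- fit_one_inflated(eq5d_t ~ 1, eq5d_t ~ 1, d1)
    diagnostics$eq5d <- list(
      r2 = cox_snell_r2(eq_fit$loglik, eq_null$loglik, eq_fit$n),
      outliers = which(flag_outliers(eq_fit, seed = cfg$seed)))
  }

  manifest <- list(
    n = nrow(data), m = cfg$m, burn_in = cfg$burn_in, B = cfg$B,
    seed = cfg$seed, include_children = cfg$include_children,
    transform = list(n = spec$n, min_index = spec$min_index,
                     max_index = spec$max_index),
    formulas = lapply(formulas[parts], deparse1),
    package_version = as.character(utils::packageVersion("qolnorm")))

  out <- structure(list(spec = spec, imputed = imputed,
                        stacks = stacks, selection = selection,
                        pooled = pooled, norms = norms,
                        diagnostics = diagnostics, manifest = manifest),
                   class = "qn_pipeline")
  if (!is.null(cfg$out_dir)) .write_pipeline(out, cfg$out_dir)
  out
}

.write_pipeline <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in names(out$pooled)) {
    utils::write.csv(out$pooled[[p]],
                     file.path(dir, paste0("pooled_", p, ".csv")),
                     row.names = FALSE)
  }
  for (nm in names(out$norms)) {
    for (comp in names(out$norms[[nm]]$curves)) {
      utils::write.csv(out$norms[[nm]]$curves[[comp]],
                       file.path(dir, paste0("norms_", nm, "_", comp,
                                             ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' @export
print.qn_pipeline <- function(x, ...) {
  cat("HRQoL norms pipeline run: n =", x$manifest$n, ", m =", x$manifest$m,
      ", B =", x$manifest$B, ", seed =", x$manifest$seed, "\n")
  cat("Final formulas:\n")
  for (p in names(x$manifest$formulas)) {
    cat("  ", p, ": ", x$manifest$formulas[[p]], "\n", sep = "")
  }
  cat("Cox-Snell pseudo-R2: VAS",
      signif(x$diagnostics$vas$r2, 3),
      if (!is.null(x$diagnostics$eq5d))
        paste("| EQ-5D", signif(x$diagnostics$eq5d$r2, 3)), "\n")
  invisible(x)
}
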