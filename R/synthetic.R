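#' Ground-truth configuration for the synthetic cohort generator
#'
#' Defines the generative model for a survey-like cohort: an age mix of
#' children (<13), adults (13-59) and elderly (60+), subgroup-restricted
#' covariates, a beta-distributed VAS, a one-inflated EQ-5D index, and
#' per-variable missingness rates. Defaults emulate a general-population
#' HRQoL survey of 1774 respondents with 18% children and 20% elderly;
#' default coefficients are on the logit scale and of the magnitude seen in
#' population HRQoL regressions, and default missingness rates follow the
#' per-variable survey percentages (e.g. 5% for VAS, 7% and 10% for the two
#' experience-with-severe-disease items).
#'
#' Coefficient vectors are named by columns of [truth_design()]: available
#' names are `intercept, age, age2, male, household_size, exp_self,
#' exp_family, pets, sick, child, adult, elderly, child_sick, smoking,
#' edu_none_primary, edu_higher, edu_student, health_sector, disabled,
#' school_no`.
#'
#' @param n cohort size.
#' @param age_mix named fractions (`child`, `adult`, `elderly`), summing
#'   to 1.
#' @param vas_coefs named logit-scale coefficients of the VAS mean model.
#' @param vas_precision beta precision of the VAS component (> 0).
#' @param nu_coefs named logit-scale coefficients for P(EQ-5D index = 1).
#' @param mu_coefs named logit-scale coefficients of the conditional
#'   (non-one) EQ-5D mean model.
#' @param mu_precision beta precision of the conditional EQ-5D component.
#' @param index_range nominal (min, max) of non-one EQ-5D index values used
#'   to back-transform beta draws to the index scale.
#' @param missing_rates named per-variable missingness probabilities in
#'   \eqn{[0, 1)}.
#' @param seed RNG seed used by [generate_cohort()].
#' @return object of class `qn_truth`.
#' @export
truth_config <- function(
    n = 1774,
    age_mix = c(child = 0.18, adult = 0.62, elderly = 0.20),
    vas_coefs = c(intercept = 1.25, age = 0.03, age2 = -3e-4,
                  exp_self = -0.45, exp_family = -0.20, pets = -0.16,
                  sick = -0.87, child_sick = -1.12, disabled = -0.79),
    vas_precision = 5,
    nu_coefs = c(intercept = 0.9, age = 0.04, age2 = -7e-4,
                 sick = -1.66, exp_self = -1.03, exp_family = -0.45,
                 pets = -0.37),
    mu_coefs = c(intercept = 2.63, age = -0.02, exp_self = -0.22,
                 exp_family = 0.25, child = -0.96, disabled = -0.91,
                 smoking = -0.27),
    mu_precision = 5,
    index_range = c(-0.074, 0.817),
    missing_rates = c(vas = 0.05, eq5d_index = 0.02, household_size = 0.02,
                      exp_self = 0.07, exp_family = 0.10, pets = 0.01,
                      education = 0.01, health_sector = 0.01, school = 0.01,
                      disabled = 0.01, n_grandchildren = 0.04),
    seed = NULL) {
  stopifnot(n >= 1, length(age_mix) == 3L,
            abs(sum(age_mix) - 1) < 1e-8,
            vas_precision > 0, mu_precision > 0,
            all(missing_rates >= 0), all(missing_rates < 1),
            index_range[1] < index_range[2])
  known <- .truth_columns()
  for (cf in list(vas_coefs, nu_coefs, mu_coefs)) {
    bad <- setdiff(names(cf), known)
    if (length(bad)) {
      stop("unknown coefficient name(s): ", paste(bad, collapse = ", "))
    }
  }
  structure(list(n = as.integer(n), age_mix = age_mix,
                 vas_coefs = vas_coefs, vas_precision = vas_precision,
                 nu_coefs = nu_coefs, mu_coefs = mu_coefs,
                 mu_precision = mu_precision, index_range = index_range,
                 missing_rates = missing_rates, seed = seed),
            class = "qn_truth")
}

#' @export
print.qn_truth <- function(x, ...) {
  cat("Synthetic cohort truth: n =", x$n, "| age mix",
      paste(sprintf("%s %.0f%%", names(x$age_mix), 100 * x$age_mix),
            collapse = ", "), "\n")
  cat("VAS coefs:", paste(names(x$vas_coefs), signif(x$vas_coefs, 3),
                          sep = "=", collapse = ", "), "\n")
  cat("nu coefs: ", paste(names(x$nu_coefs), signif(x$nu_coefs, 3),
                          sep = "=", collapse = ", "), "\n")
  cat("mu coefs: ", paste(names(x$mu_coefs), signif(x$mu_coefs, 3),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

.truth_columns <- function() {
  c("intercept", "age", "age2", "male", "household_size", "exp_self",
    "exp_family", "pets", "sick", "child", "adult", "elderly", "child_sick",
    "smoking", "edu_none_primary", "edu_higher", "edu_student",
    "health_sector", "disabled", "school_no")
}

#' Numeric design matrix matching the generator's coefficient names
#'
#' Expands a cohort table into the numeric columns the ground-truth
#' coefficients are named by (indicator coding: `exp_self` = 1 for "yes",
#' education dummies with "secondary" as reference, `child_sick` the
#' child-by-sick interaction, `school_no` = 1 for a child not in school).
#' Useful for fitting models whose coefficient names align exactly with the
#' generating truth.
#'
#' @param cohort a cohort table from [generate_cohort()].
#' @return numeric matrix, one column per name in `.truth_columns`.
#' @export
truth_design <- function(cohort) {
  yes <- function(v) as.numeric(!is.na(v) & v == "yes")
  child <- as.numeric(cohort$group == "child")
  adult <- as.numeric(cohort$group == "adult")
  elderly <- as.numeric(cohort$group == "elderly")
  sick <- yes(cohort$sick)
  m <- cbind(
    intercept = 1,
    age = cohort$age,
    age2 = cohort$age^2,
    male = as.numeric(cohort$gender == "male"),
    household_size = cohort$household_size,
    exp_self = yes(cohort$exp_self),
    exp_family = yes(cohort$exp_family),
    pets = yes(cohort$pets),
    sick = sick,
    child = child, adult = adult, elderly = elderly,
    child_sick = child * sick,
    smoking = yes(cohort$smoking),
    edu_none_primary = as.numeric(cohort$education == "none_primary"),
    edu_higher = as.numeric(cohort$education == "higher"),
    edu_student = as.numeric(cohort$education == "student"),
    health_sector = yes(cohort$health_sector),
    disabled = yes(cohort$disabled),
    school_no = child * as.numeric(!is.na(cohort$school) &
                                     cohort$school == "no"))
  rownames(m) <- NULL
  m
}

.lp <- function(design, coefs) {
  lp <- drop(design[, names(coefs), drop = FALSE] %*% coefs)
  if (any(!is.finite(lp))) stop("non-finite linear predictor")
  lp
}

#' Generate a complete synthetic survey cohort
#'
#' Draws a respondent-level table emulating a general-population HRQoL
#' survey: ages 0-99 split into child/adult/elderly blocks, covariates that
#' exist only within their block (carrying the explicit level `"irrelevant"`
#' outside it, or `NA`-by-design for the subgroup-restricted continuous
#' variable), VAS drawn as \eqn{100 \times Beta(\mu\phi, (1-\mu)\phi)} with
#' \eqn{\mu} the logistic of the configured linear predictor, and an EQ-5D
#' index drawn as exactly 1 with probability given by the nu predictor, or
#' otherwise back-transformed from a beta draw on the mu predictor. EQ-5D
#' dimension levels consistent with the index (all level 1 if and only if
#' the index is 1) are derived for structural completeness. The output has
#' no missing cells except the by-design blanks; add survey-like missingness
#' with [inject_missingness()].
#'
#' @param cfg a [truth_config()].
#' @return a `data.frame` cohort table; the truth configuration is attached
#'   as attribute `"truth"`.
#' @export
generate_cohort <- function(cfg = truth_config()) {
  stopifnot(inherits(cfg, "qn_truth"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n
  group <- factor(sample(c("child", "adult", "elderly"), n, replace = TRUE,
                         prob = cfg$age_mix[c("child", "adult", "elderly")]),
                  levels = c("child", "adult", "elderly"))
  age <- integer(n)
  age[group == "child"] <- sample(0:12, sum(group == "child"), TRUE)
  age[group == "adult"] <- sample(13:59, sum(group == "adult"), TRUE)
  age[group == "elderly"] <- sample(60:99, sum(group == "elderly"), TRUE)

  yn <- function(p, idx = rep(TRUE, n)) {
    v <- factor(rep("irrelevant", n),
                levels = c("no", "yes", "irrelevant"))
    v[idx] <- ifelse(stats::runif(sum(idx)) < p, "yes", "no")
    if (all(idx)) droplevels(v) else v
  }
  adult_eld <- group %in% c("adult", "elderly")
  is_child <- group == "child"

  d <- data.frame(
    id = seq_len(n), age = age, group = group,
    gender = factor(ifelse(stats::runif(n) < 0.46, "male", "female")),
    household_size = pmin(1L + stats::rpois(n, 1.5), 12L),
    exp_self = yn(0.17), exp_family = yn(0.54), pets = yn(0.60),
    sick = yn(0.03),
    smoking = yn(0.17, adult_eld),
    education = factor(rep("irrelevant", n),
                       levels = c("secondary", "none_primary", "higher",
                                  "student", "irrelevant")),
    health_sector = yn(0.22, adult_eld),
    disabled = yn(0.02, adult_eld),
    school = yn(0.75, is_child),
    n_grandchildren = NA_real_)
  d$education[adult_eld] <- sample(
    c("none_primary", "secondary", "higher", "student"),
    sum(adult_eld), TRUE, prob = c(0.08, 0.30, 0.52, 0.10))
  d$n_grandchildren[group == "elderly"] <-
    stats::rpois(sum(group == "elderly"), 2.5)

  X <- truth_design(d)
  mu_vas <- stats::plogis(.lp(X, cfg$vas_coefs))
  vas <- 100 * stats::rbeta(n, mu_vas * cfg$vas_precision,
                            (1 - mu_vas) * cfg$vas_precision)
  d$vas <- pmin(pmax(vas, 1e-6), 100 - 1e-6)

  p1 <- stats::plogis(.lp(X, cfg$nu_coefs))
  is_one <- stats::runif(n) < p1
  mu_eq <- stats::plogis(.lp(X, cfg$mu_coefs))
  z <- stats::rbeta(n, mu_eq * cfg$mu_precision,
                    (1 - mu_eq) * cfg$mu_precision)
  z <- pmin(pmax(z, 1e-9), 1 - 1e-9)
  index <- cfg$index_range[1] + z * diff(cfg$index_range)
  index[is_one] <- 1
  d$eq5d_index <- index

  dims <- .derive_dimensions(index, cfg$index_range)
  d <- cbind(d, dims)
  attr(d, "truth") <- cfg
  d
}

## EQ-5D-3L dimension levels loosely consistent with a continuous index:
## all dimensions at level 1 iff the index is exactly 1; otherwise severity
## increases as the index falls.
.derive_dimensions <- function(index, index_range) {
  n <- length(index)
  sev <- 1 - (index - index_range[1]) / (1 - index_range[1])
  sev[index == 1] <- 0
  out <- matrix(1L, n, 5,
                dimnames = list(NULL, c("mobility", "selfcare", "usual",
                                        "pain", "anxiety")))
  for (j in 1:5) {
    u <- stats::runif(n)
    out[, j] <- 1L + (u < sev) + (u < sev^2)
  }
  nonone <- index != 1
  all1 <- nonone & rowSums(out > 1L) == 0L
  out[all1, "pain"] <- 2L
  out[index == 1, ] <- 1L
  as.data.frame(out)
}

#' Inject survey-like missingness into a cohort
#'
#' Masks cells of maskable variables with the configured per-variable rates.
#' The default mechanism is MCAR (each eligible cell independently missing
#' with its variable's rate); `mechanism = "mar_age"` makes the missingness
#' log-odds depend linearly on centred age with slope `mar_slope`
#' (slope 0 reduces to MCAR). Cells that are "irrelevant" or blank by design
#' outside a variable's subgroup are never masked.
#'
#' @param cohort a cohort table from [generate_cohort()].
#' @param missing_rates named per-variable rates; defaults to the rates in
#'   the cohort's attached truth configuration.
#' @param seed RNG seed.
#' @param mechanism `"mcar"` or `"mar_age"`.
#' @param mar_slope log-odds slope on centred age for `"mar_age"`.
#' @return the cohort with masked cells set to `NA` (and subgroup factors
#'   keeping their `"irrelevant"` level).
#' @export
inject_missingness <- function(cohort, missing_rates = NULL, seed = NULL,
                               mechanism = c("mcar", "mar_age"),
                               mar_slope = 0) {
  mechanism <- match.arg(mechanism)
  if (is.null(missing_rates)) {
    tr <- attr(cohort, "truth")
    if (is.null(tr)) stop("no missing_rates given and no truth attached")
    missing_rates <- tr$missing_rates
  }
  bad <- setdiff(names(missing_rates), names(cohort))
  if (length(bad)) {
    stop("missing rate for unknown variable(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  age_c <- cohort$age - mean(cohort$age)
  for (v in names(missing_rates)) {
    rate <- missing_rates[[v]]
    if (rate <= 0) next
    col <- cohort[[v]]
    eligible <- !is.na(col)
    if (is.factor(col) && "irrelevant" %in% levels(col)) {
      eligible <- eligible & col != "irrelevant"
    }
    p <- if (mechanism == "mcar") rate else
      stats::plogis(stats::qlogis(rate) + mar_slope * age_c)
    mask <- eligible & stats::runif(nrow(cohort)) < p
    cohort[[v]][mask] <- NA
  }
  cohort
}
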