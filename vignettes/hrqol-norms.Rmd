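---
title: "Modelling bounded, one-inflated quality-of-life outcomes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bounded, one-inflated quality-of-life outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qolnorm)
```

## The outcomes and why ordinary regression fails on them

General-population HRQoL surveys yield two outcomes per respondent: a VAS
self-rating on 0–100 and an EQ-5D-3L profile — five dimensions (mobility,
self-care, usual activities, pain, anxiety/depression) at three levels —
which a country *tariff* converts into a single utility index on
$(-\infty, 1]$, with 1 meaning perfect health. Both outcomes are bounded,
right-shifted (most people are healthy), and the index has a large point
mass at exactly 1. A Gaussian linear model violates the bounds, ignores the
mass, and gets the heteroscedasticity backwards (variance shrinks near the
bounds).

`qolnorm` therefore uses the beta distribution in its mean/precision
parameterization, $y \sim \mathrm{Beta}(\mu\phi, (1-\mu)\phi)$ with
$\mathrm{E}[y] = \mu$, $\mathrm{Var}[y] = \mu(1-\mu)/(1+\phi)$, a logit
link for $\mu$ and a log link for $\phi$. (gamlss users: our $\phi$ relates
to the BE family's $\sigma$ by $\sigma^2 = 1/(1+\phi)$;
`phi_to_sigma()` / `sigma_to_phi()` round-trip the conversion exactly. For
the inflated family, gamlss parameterizes the mass as an odds $\nu$ with a
log link; our logit on $p_1$ is the same model since
$\log \nu = \mathrm{logit}(p_1)$.)

## Getting the outcomes into the beta support

The beta support is the *open* interval, so:

* VAS is divided by 100 and shrunk, $y' = (y(N-1) + 0.5)/N$, where $N$ is
  the number of respondent rows in the dataset being transformed. $N$ is
  counted over all rows (not just rows with an observed outcome), is fixed
  before imputation, and is reused by every imputed copy, so transformed
  values are comparable across the stack.
* the EQ-5D index keeps its mass at 1 untouched; the non-one values are
  first mapped affinely onto $[0,1]$ using the observed minimum and maximum
  of the non-one values, then shrunk with the same formula. The observed
  min/max and $N$ are stored in a `transform_spec` so that predictions can
  be mapped back to the index scale consistently. Because the PMM imputer
  only ever imputes observed values, imputation cannot move the observed
  min/max, which is what makes "compute the spec once, reuse everywhere"
  coherent.

Both maps are strictly increasing and exactly invertible
(`inverse_shrink()`, `denormalize_index()`), which is how all predictions
are reported on the original scales.

## Estimation

`fit_beta_regression()` maximizes the exact beta log-likelihood over
$(\beta, \log\phi)$ by Fisher scoring — quasi-Newton ascent using the
analytic score and the expected information — with step-halving, so the
log-likelihood trace is non-decreasing by construction (it is stored in the
fit as `loglik_trace`). Starting values are OLS on the logit-transformed
outcome and a method-of-moments $\phi$; convergence is declared at a
relative log-likelihood change below $10^{-10}$ (default; bootstrap refits
use $10^{-8}$, far below resampling noise), with a BFGS polish as fallback
if scoring stalls. Standard errors come from the inverse expected
information, which is positive definite and much better conditioned than a
finite-difference Hessian when covariates live on very different scales
(age and age²).

`fit_one_inflated()` exploits the exact factorization of the one-inflated
likelihood: the nu part *is* a logistic regression of the perfect-health
indicator (fitted with `stats::glm`), the mu part *is* a beta regression of
the non-one rows, and the joint log-likelihood is their sum. Degenerate
mixtures (no ones, all ones, fewer than two distinct non-one values) are
refused with a pointer to the single-component model. Very large nu
coefficients trigger a quasi-separation warning: with few non-perfect
respondents in some stratum the Wald covariance is unreliable, and the
bootstrap route below is the authoritative source of uncertainty.

Diagnostics: randomized quantile residuals map each observation through the
fitted CDF and $\Phi^{-1}$; only the mass at 1 requires randomization (a
uniform draw on $(1-\hat p_{1i}, 1)$, deterministic given a seed). For
non-one observations under the inflated model the CDF is
$(1-p_1)F_\beta(y)$. Cox–Snell pseudo-R²
$= 1 - \exp(-\tfrac{2}{n}(\ell_{full}-\ell_{null}))$ uses the
intercept-only fit (both submodels intercept-only for the inflated case) as
the null. Observations with $|r| > 3.5$ are flagged as outliers; the
default is to keep them, with refits excluding them available to the user.

## Multiple imputation

`impute_fcs()` implements fully conditional specification: initialize
missing cells by sampling observed values, then cycle through the variables
(ascending missingness order — a convention, the order is not
statistically loaded) regressing each on all other allowed predictors and
redrawing its missing cells, for a burn-in of 5 iterations (default) in
each of $m = 5$ independent chains. Methods per variable type:

* continuous: predictive mean matching. Regression parameters are drawn
  from their approximate posterior, each missing case's donor pool is the
  `donor_k = 5` observed cases with the closest predicted means, and one
  donor's observed value is imputed. PMM is used because VAS and the index
  are distinctly non-normal; imputations stay in the observed support by
  construction. `donor_k = 5` is the conventional default.
* binary factors: logistic regression with a small ridge penalty that is
  escalated automatically when separation is detected (coefficients
  diverging). This stabilization is why no per-variable fallback to trees
  is *needed*, but `method = "cart"` (rpart) is available for any variable.
* factors with 3+ levels: multinomial regression (`nnet::multinom`).

Subgroup-restricted categorical variables (e.g. smoking, only asked of
adults and elderly) carry an explicit `"irrelevant"` level outside their
subgroup; those cells are by design, never imputed, and the imputation
model for such a variable is fitted within its subgroup only. Restricted
*continuous* variables (number of grandchildren, elderly only) are imputed
and then blanked outside the subgroup by post-processing, and are excluded
from every predictor set.

Chain health is summarized by `check_convergence()`: a variable is flagged
when all chains drift in the same direction between the first and second
half of the iterations and the mean drift is large relative to the
between-chain spread (one-sample $t$ above the 1% critical value). A plain
"monotone over the last half" rule would flag stationary noise about a
third of the time with 5 iterations; the $t$-form keeps the false-flag rate
near the nominal 1%.

## Selection, pooling, norms

**Selection** is two-step. Step one: fit the model on each imputed dataset,
Wald-test each term (factors as a block — removing "a covariate" means the
whole variable), and drop a term only when it is non-significant
($p > 0.05$) in *all* $m$ datasets; among removable terms the one whose
best across-dataset p-value is largest goes first, one per round, ties
broken lexicographically, so the procedure is fully deterministic and
replayable. The source description of this rule is grammatically ambiguous
("not significant in any of the datasets"); we read it as
keep-if-significant-somewhere, and `rule = "any"` provides the opposite
reading. The age polynomial and subgroup indicators are forced in. The
quadratic-implies-linear convention is the caller's responsibility when
writing formulas. Step two: many-level factors are recoded by candidate
level merges (user-supplied, or enumerated from pairwise non-significant
level contrasts), the winner being the coding with the lowest mean AIC
across the $m$ datasets; AIC's invariance to the reference category is
verified numerically rather than assumed.

**Pooling.** Observed-information covariances for these models can be
fragile (quasi-separation in the nu part; small non-one subsets in the mu
part), so coefficient uncertainty is bootstrapped: $B = 500$ nonparametric
row resamples per imputed dataset, the per-dataset estimate being the mean
of the $B$ replicate coefficient vectors and the per-dataset variance their
empirical (co)variance — deliberately the plain variance, no bias
correction. Rubin's rules then give the pooled estimate, within-variance
$W$, between-variance $B$, total $T = W + (1+1/m)B$ and
$\lambda = (1+1/m)B/T$; intervals use a $t$ reference with Barnard–Rubin
degrees of freedom (the large-sample limit by default, reducing to the
complete-data df when $B = 0$). Resampling is by respondent row,
unstratified, matching the survey's sampling unit; stratified resampling is
available. Replicates are warm-started from the full-data fit with a
cold-start fallback; failed replicates are excluded and counted, and more
than 10% failures aborts.

**Norm curves.** `fit_age_norms()` fits intercept + age + age² in every
submodel (quadratics were chosen over splines/fractional polynomials as
they fit comparably and extrapolate more predictably; this is also why the
curves should not be read outside the observed age range — extrapolation
warns). `predict_norms_ci()` bootstraps the whole curve: per imputed
dataset, $B$ resample-refit-predict passes over the age grid; the pooled
band is the 2.5%/97.5% percentile of all $m \times B$ replicate curves and
the point estimate is their median — the median is used precisely so the
"band contains the point" invariant holds at every age by construction;
the mean of the $m$ full-data fits is reported alongside as `mean_fit`.
For the EQ-5D the curve comes in three components: $p_1(\text{age})$, the
conditional mean index among the non-perfect, and the overall mean
$p_1 + (1-p_1)\,\mathrm{E}[\text{index} \mid \text{index} < 1]$.
Norms are also reported from the full determinant model by averaging
row-level predictions within each age — a declared marginalization
convention, since covariate-adjusted "population averages" can be formed in
more than one way.

The sensitivity branch (`include_children = FALSE`) repeats everything on
adults and elderly only, because child questionnaires are proxy-completed
and adult valuation of child health states is contested.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code, not a fixture: it defines
the study conditions under which the pipeline is validated. Defaults: 1774
respondents, 18% children (<13), 20% elderly (60+), ages uniform within
blocks; covariates with survey-like prevalences (17% disease experience
with oneself, 54% with a family member, 60% pet owners, 3% sick on the
survey day, education at four levels for adults/elderly, school status for
children, grandchildren counts for elderly); VAS drawn as
$100\times\mathrm{Beta}(\mu\phi,(1-\mu)\phi)$ with
$\mathrm{logit}(\mu) = 1.25 + 0.03\,\text{age} - 0.0003\,\text{age}^2 -
0.45\,\text{selfdisease} - \dots$ and $\phi = 5$; the EQ-5D index equal to
1 with probability $\mathrm{logit}^{-1}$ of its own predictor and
otherwise mapped from a beta draw onto the nominal index range
$(-0.074, 0.817)$. The coefficient magnitudes are rounded values typical of
population HRQoL regressions, so synthetic runs resemble a real survey
analysis; all are overridable, and parameter-recovery tests fit models on
exactly these generating columns (`truth_design()`).

Missingness defaults mirror per-variable survey rates (5% VAS, 2% index,
7%/10% for the two disease-experience items, 1–4% elsewhere) under MCAR;
an MAR-on-age switch exists because MAR is the assumption FCS actually
needs, and a zero slope provably reduces to MCAR. What the generator does
*not* emulate: quota sampling and household recruitment, response
propensity, dimension-level response patterns (dimension levels are derived
from the index, not jointly modelled), or informative missingness — so
green tests certify the statistical machinery under its stated assumptions,
not robustness to violations a real survey might contain.

One deliberate asymmetry: the generator back-transforms beta draws through
the *nominal* index range, while the analysis pipeline normalizes by the
*observed* non-one range, as one must with real data. Recovery tests
therefore build their transform spec from the nominal range; the pipeline
default remains the observed range.

A tariff is needed to exercise scoring; since country value sets are
published externally, the package ships a clearly labelled *synthetic*
Belgian-style tariff (`inst/extdata/tariff_belgium_synthetic.csv`)
constructed so its 243-profile range is exactly $[-0.074, 1]$, the range of
the real Belgian set. It is a structural stand-in for testing, not the
published coefficients.

## Numerical choices and degenerate inputs

* Convergence: relative log-likelihood change $< 10^{-10}$, max 200
  scoring iterations, BFGS fallback; $\log\phi$ capped at 30 against
  overflow.
* A numerically constant response returns a capped perfect-fit warning
  ($\phi$ unbounded) instead of a divergent optimization.
* Rank-deficient designs error, naming the aliased columns (imputation
  drops collinear predictor columns instead, with one summary warning —
  structural collinearities like "irrelevant ⇔ child" are routine there).
* Model CDF values of exactly 0/1 in residuals are clamped with a warning.
* Elimination that empties a model returns intercept-only with a warning;
  factor merges that would empty a level are skipped with a warning.
* All RNG consumers take explicit seeds; one master seed derives every
  stage seed in `run_pipeline()`, and the manifest records them, so reruns
  are bit-reproducible.

## Problem sizes used by the test suite

The simulation-based checks are sized to single-CPU runs: coefficient
recovery and CI coverage use 100 cohorts of n = 2000 (coverage through the
full impute → bootstrap (B = 100) → Rubin chain at m = 5), type-I retention
of a noise covariate uses 200 cohorts of n = 800, and the distributional
residual check uses one cohort of n = 10,000. The acceptance script runs
the complete pipeline once at the default survey size (n = 1774, m = 5,
B = 500).

## Known limitations

* The index is treated as continuous although EQ-5D-3L has only 243
  states; dimension-level modelling is out of scope.
* Quadratic age curves fit mid-life well but are the weakest at the age
  extremes; norms from the full determinant model are reported alongside
  for that reason.
* Backward elimination on per-dataset fits (rather than on Rubin-pooled
  Wald tests) slightly favours covariates that shine in any single imputed
  dataset; the same data drive selection, recategorization and estimation,
  so some over-fitting optimism is inherent to the design.
* The bootstrap treats the survey as i.i.d. rows; design weights and
  clustering are not modelled.
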