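#' Shrink a unit-interval value away from the boundaries
#'
#' Beta regression requires outcomes strictly inside (0, 1). Values on
#' \eqn{[0, 1]} are shrunk towards 1/2 using the sample-size-dependent map
#' \deqn{y' = (y (N - 1) + 0.5) / N,}
#' the standard boundary-avoiding transform for bounded outcomes. The map is
#' strictly increasing, fixes 1/2, and sends 0 to \eqn{0.5/N} and 1 to
#' \eqn{(N - 0.5)/N}, so the output always lies in the open interval.
#'
#' @param y numeric vector in \eqn{[0, 1]} (e.g. VAS/100, or a normalized
#'   EQ-5D index).
#' @param n sample size \eqn{N \ge 2}: the number of respondent rows in the
#'   dataset being transformed.
#' @return numeric vector strictly inside (0, 1).
#' @seealso [inverse_shrink()] for the inverse map.
#' @examples
#' shrink_transform(c(0, 0.5, 1), n = 100)
#' @export
shrink_transform <- function(y, n) {
  stopifnot(is.numeric(y), length(n) == 1L, n >= 2)
  bad <- !is.na(y) & (y < 0 | y > 1)
  if (any(bad)) {
    stop("shrink_transform: values outside [0, 1]: ",
         paste(utils::head(signif(y[bad], 4), 5), collapse = ", "))
  }
  (y * (n - 1) + 0.5) / n
}

#' Invert the boundary shrink transform
#'
#' Recovers the original \eqn{[0, 1]} value from a shrunken one, so fitted
#' means can be reported on the outcome's original scale.
#'
#' @param z numeric vector strictly inside (0, 1).
#' @param n the sample size used in the forward transform.
#' @return numeric vector in \eqn{[0, 1]} (up to numerical tolerance).
#' @export
inverse_shrink <- function(z, n) {
  stopifnot(is.numeric(z), length(n) == 1L, n >= 2)
  bad <- !is.na(z) & (z <= 0 | z >= 1)
  if (any(bad)) stop("inverse_shrink: values outside (0, 1)")
  (z * n - 0.5) / (n - 1)
}

#' Normalize an EQ-5D index value onto [0, 1]
#'
#' The EQ-5D index can be negative (states valued worse than death), so
#' non-one index values are first mapped affinely onto \eqn{[0, 1]} using the
#' observed minimum and maximum of the non-one values,
#' \deqn{y' = (y - \min) / (\max - \min),}
#' before the boundary shrink is applied. Applied to non-one values only; the
#' point mass at 1 is modelled separately.
#'
#' @param y numeric vector of (non-one) EQ-5D index values.
#' @param min_index,max_index observed minimum and maximum of the non-one
#'   index values.
#' @return numeric vector in \eqn{[0, 1]}.
#' @export
normalize_index <- function(y, min_index, max_index) {
  stopifnot(is.numeric(y))
  if (!(min_index < max_index)) {
    stop("normalize_index: degenerate range, min_index must be < max_index")
  }
  (y - min_index) / (max_index - min_index)
}

#' @rdname normalize_index
#' @param z normalized value in \eqn{[0, 1]} to map back to the index scale.
#' @export
denormalize_index <- function(z, min_index, max_index) {
  stopifnot(min_index < max_index)
  min_index + z * (max_index - min_index)
}

#' Transform specification for a dataset
#'
#' Records the constants needed to transform outcomes reproducibly: the
#' sample size N used by the shrink transform and the observed min/max of
#' the non-one EQ-5D index values used by the normalization. Storing them
#' once means predictions from any fit can be back-transformed consistently,
#' and every imputed copy of a dataset reuses the same constants.
#'
#' @param n sample size (number of respondent rows), at least 2.
#' @param min_index,max_index observed range of the non-one EQ-5D index
#'   values (ignored when only VAS is transformed).
#' @return an object of class `qn_transform_spec`.
#' @export
transform_spec <- function(n, min_index = NA_real_, max_index = NA_real_) {
  stopifnot(length(n) == 1L, n >= 2)
  if (!is.na(min_index) && !is.na(max_index) && !(min_index < max_index)) {
    stop("transform_spec: min_index must be < max_index")
  }
  structure(list(n = as.integer(n), min_index = min_index,
                 max_index = max_index),
            class = "qn_transform_spec")
}

#' @export
print.qn_transform_spec <- function(x, ...) {
  cat("Outcome transform spec: N =", x$n)
  if (!is.na(x$min_index)) {
    cat(", non-one index range [", x$min_index, ", ", x$max_index, "]",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Transform VAS and EQ-5D outcomes for beta-family modelling
#'
#' `transform_vas()` divides VAS (0-100) by 100 and shrinks it into (0, 1);
#' `transform_eq5d()` leaves perfect-health values (index exactly 1) alone
#' and maps non-one values through normalization then the shrink, so the
#' result is exactly 1 for the inflated mass and strictly inside (0, 1)
#' otherwise. `backtransform_vas()` / `backtransform_eq5d()` invert the
#' chains to the original scales.
#'
#' @param vas numeric VAS scores in \eqn{[0, 100]}.
#' @param spec a [transform_spec()].
#' @return numeric vector on the transformed (or original) scale.
#' @export
transform_vas <- function(vas, spec) {
  stopifnot(inherits(spec, "qn_transform_spec"))
  if (any(!is.na(vas) & (vas < 0 | vas > 100))) {
    stop("transform_vas: VAS outside [0, 100]")
  }
  shrink_transform(vas / 100, spec$n)
}

#' @rdname transform_vas
#' @param z transformed values in (0, 1).
#' @export
backtransform_vas <- function(z, spec) {
  stopifnot(inherits(spec, "qn_transform_spec"))
  100 * inverse_shrink(z, spec$n)
}

#' @rdname transform_vas
#' @param index numeric EQ-5D index values; values equal to 1 are the
#'   inflated perfect-health mass.
#' @export
transform_eq5d <- function(index, spec) {
  stopifnot(inherits(spec, "qn_transform_spec"))
  if (is.na(spec$min_index) || is.na(spec$max_index)) {
    stop("transform_eq5d: spec carries no index range; ",
         "build it with transform_spec(n, min_index, max_index)")
  }
  out <- index
  nonone <- !is.na(index) & index != 1
  out[nonone] <- shrink_transform(
    normalize_index(index[nonone], spec$min_index, spec$max_index), spec$n)
  out
}

#' @rdname transform_vas
#' @export
backtransform_eq5d <- function(z, spec) {
  stopifnot(inherits(spec, "qn_transform_spec"))
  out <- z
  nonone <- !is.na(z) & z != 1
  out[nonone] <- denormalize_index(inverse_shrink(z[nonone], spec$n),
                                   spec$min_index, spec$max_index)
  out
}

#' Survey completion rate
#'
#' Percentage of approached individuals who completed the questionnaire.
#'
#' @param completed,approached counts of completed and approached
#'   individuals.
#' @return completion percentage on the 0-100 scale.
#' @export
completion_rate <- function(completed, approached) {
  stopifnot(completed >= 0, approached > 0, completed <= approached)
  100 * completed / approached
}
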