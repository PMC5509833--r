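#' Read an EQ-5D-3L tariff (value set) table
#'
#' A tariff maps an EQ-5D-3L profile (five dimensions, levels 1-3) to a
#' utility index by subtracting additive decrements from the full-health
#' value of 1. The file is delimited text with header
#' `term,dimension,level,value`:
#' \itemize{
#'   \item `term = "constant"` rows: subtracted once whenever any dimension
#'     is above level 1 (the "any problem" constant; `dimension`/`level`
#'     empty).
#'   \item `term = "decrement"` rows: subtracted when `dimension`
#'     (1 = mobility, 2 = self-care, 3 = usual activities, 4 = pain,
#'     5 = anxiety/depression) is at `level` (2 or 3).
#' }
#' Country value sets (e.g. the Belgian set, with index range
#' \eqn{[-0.074, 1]}) are published externally and supplied by the user; a
#' synthetic Belgian-style tariff with that exact range ships with the
#' package for testing (`system.file("extdata", "tariff_belgium_synthetic.csv",
#' package = "qolnorm")`).
#'
#' @param path path to the tariff CSV.
#' @return an object of class `qn_tariff`: list with `constant` (numeric) and
#'   `decrements` (5 x 3 matrix, column j = decrement for level j; level 1
#'   column is zero).
#' @export
read_tariff <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("term", "dimension", "level", "value")
  if (!all(need %in% names(tab))) {
    stop("read_tariff: file must have columns ", paste(need, collapse = ", "))
  }
  dec <- matrix(0, nrow = 5, ncol = 3,
                dimnames = list(
                  c("mobility", "selfcare", "usual", "pain", "anxiety"),
                  paste0("level", 1:3)))
  constant <- 0
  for (i in seq_len(nrow(tab))) {
    if (tab$term[i] == "constant") {
      constant <- constant + tab$value[i]
    } else if (tab$term[i] == "decrement") {
      d <- as.integer(tab$dimension[i]); l <- as.integer(tab$level[i])
      if (is.na(d) || is.na(l) || d < 1 || d > 5 || l < 2 || l > 3) {
        stop("read_tariff: bad (dimension, level) = (",
             tab$dimension[i], ", ", tab$level[i], ") on row ", i)
      }
      dec[d, l] <- dec[d, l] + tab$value[i]
    } else {
      stop("read_tariff: unknown term '", tab$term[i], "'")
    }
  }
  structure(list(constant = constant, decrements = dec), class = "qn_tariff")
}

#' @export
print.qn_tariff <- function(x, ...) {
  rng <- range(score_eq5d(eq5d_profiles(), x))
  cat("EQ-5D-3L tariff: any-problem constant", x$constant,
      "| index range over 243 profiles [", signif(rng[1], 4), ",",
      signif(rng[2], 4), "]\n")
  invisible(x)
}

#' All 243 EQ-5D-3L profiles
#'
#' @return a 243 x 5 integer matrix, one row per profile, columns in
#'   dimension order (mobility, self-care, usual activities, pain,
#'   anxiety/depression).
#' @export
eq5d_profiles <- function() {
  m <- as.matrix(expand.grid(rep(list(1:3), 5), KEEP.OUT.ATTRS = FALSE))
  storage.mode(m) <- "integer"
  colnames(m) <- c("mobility", "selfcare", "usual", "pain", "anxiety")
  m
}

#' Score EQ-5D-3L profiles with a tariff
#'
#' Applies the additive scoring algorithm: start from 1 (full health),
#' subtract the any-problem constant if any dimension exceeds level 1, and
#' subtract the per-dimension level decrements. Profile (1,1,1,1,1) always
#' scores exactly 1.
#'
#' @param profile integer vector of length 5 (levels in 1..3), or a matrix
#'   with 5 columns, one profile per row.
#' @param tariff a `qn_tariff` from [read_tariff()].
#' @return numeric index score(s).
#' @export
score_eq5d <- function(profile, tariff) {
  stopifnot(inherits(tariff, "qn_tariff"))
  if (is.vector(profile)) profile <- matrix(profile, nrow = 1)
  profile <- as.matrix(profile)
  if (ncol(profile) != 5L) stop("score_eq5d: a profile has 5 dimensions")
  if (any(is.na(profile)) || any(!profile %in% 1:3)) {
    stop("score_eq5d: levels must be in {1, 2, 3}")
  }
  dec <- tariff$decrements
  score <- rep(1, nrow(profile))
  any_problem <- rowSums(profile > 1) > 0
  score[any_problem] <- score[any_problem] - tariff$constant
  for (d in 1:5) {
    score <- score - unname(dec[d, ])[profile[, d]]  # level-1 column is zero
  }
  drop(score)
}
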