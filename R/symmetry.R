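#' Between-leg symmetry index
#'
#' Ratio-based symmetry index between the affected (AL) and unaffected
#' (UL) leg values of a biomechanical variable:
#' \code{SI = (AL - UL) / (0.5 * (AL + UL))}. Zero means perfect
#' symmetry; positive means the affected-leg value is larger; for
#' positive inputs the index is bounded in (-2, 2) and is antisymmetric
#' under swapping the legs.
#'
#' @param var_AL,var_UL trial-level per-leg means of the variable
#'   (vectorised).
#' @return Dimensionless symmetry index.
#' @export
symmetry_index <- function(var_AL, var_UL) {
  denom <- 0.5 * (var_AL + var_UL)
  if (any(denom == 0))
    stop("degenerate-input error: var_AL + var_UL must be nonzero",
         call. = FALSE)
  (var_AL - var_UL) / denom
}

#' Symmetry indices for a trial summary
#'
#' Applies [symmetry_index()] to the per-leg trial means of every
#' metric, giving one SI per biomechanical variable.
#'
#' @param summary a \code{trial_summary} from [summarize_trial()].
#' @param variables which metric columns to use; defaults to all shared
#'   numeric metrics.
#' @return Named numeric vector of symmetry indices.
#' @export
symmetry_indices <- function(summary, variables = NULL) {
  pl <- summary$per_leg
  al <- pl[pl$leg == "AL", , drop = FALSE]
  ul <- pl[pl$leg == "UL", , drop = FALSE]
  if (is.null(variables))
    variables <- setdiff(names(pl)[vapply(pl, is.numeric, logical(1))],
                         c("n_steps", "delta_rsp"))
  si <- vapply(variables, function(v)
    symmetry_index(al[[v]], ul[[v]]), numeric(1))
  stats::setNames(si, paste0("si_", variables))
}

#' One-sample t-test of symmetry indices against zero
#'
#' Tests whether a sample of symmetry indices differs from perfect
#' symmetry (SI = 0), two-sided.
#'
#' @param x numeric sample of SI values.
#' @param mu0 null value, 0 by default.
#' @return List with \code{t}, \code{df} and \code{p}.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  if (length(x) < 2)
    stop("degenerate-sample error: need at least 2 values", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate-sample error: sample variance is zero", call. = FALSE)
  tt <- stats::t.test(x, mu = mu0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Bonferroni correction
#'
#' Adjusts p-values for \code{m} comparisons as \code{min(1, p * m)}.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @param m number of comparisons (defaults to \code{length(p)}).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, p * m)
}

#' Percent difference between group means
#'
#' Difference of a group mean from a reference mean, expressed as a
#' percentage of the reference: \code{100 * (a - b) / b}, rounded to one
#' decimal for reporting (pass \code{digits = NULL} for the raw value).
#'
#' @param a group mean.
#' @param b reference mean (must be positive).
#' @param digits decimals for reporting; \code{NULL} disables rounding.
#' @return Percent difference.
#' @examples
#' percent_difference(8.18, 7.39)  # 10.7
#' @export
percent_difference <- function(a, b, digits = 1) {
  if (any(b <= 0))
    stop("reference error: reference mean must be positive", call. = FALSE)
  d <- 100 * (a - b) / b
  if (!is.null(digits)) d <- round(d, digits)
  d
}
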