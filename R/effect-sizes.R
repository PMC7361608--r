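#' Partial eta-squared from an F statistic
#'
#' `F * df1 / (F * df1 + df2)`: the proportion of effect-plus-error
#' variance attributable to the effect, recoverable from any printed F and
#' its degrees of freedom. For a one-way design this equals
#' `SSB / (SSB + SSW)` exactly.
#'
#' @param F F statistic, non-negative.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Partial eta-squared in `[0, 1]`.
#' @examples
#' partial_eta_sq(5.50, 1, 226)  # ~ .024
#' @export
partial_eta_sq <- function(F, df1, df2) {
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be positive", call. = FALSE)
  if (F < 0) stop("F must be non-negative", call. = FALSE)
  F * df1 / (F * df1 + df2)
}

#' Multivariate eta-squared from Wilks lambda (two-group case)
#'
#' For a two-group multivariate test, `1 - lambda` is the multivariate
#' partial eta-squared.
#'
#' @param lambda Wilks lambda in `(0, 1]`.
#' @return `1 - lambda`.
#' @examples
#' eta_sq_from_wilks(0.33)  # .67
#' @export
eta_sq_from_wilks <- function(lambda) {
  if (lambda <= 0 || lambda > 1) stop("lambda must lie in (0, 1]", call. = FALSE)
  1 - lambda
}

# solve pf(F, df1, df2, ncp = lambda) = target for lambda (pf decreasing in ncp)
invert_ncf <- function(F, df1, df2, target) {
  if (stats::pf(F, df1, df2, ncp = 0) <= target) return(0)
  hi <- 1
  while (stats::pf(F, df1, df2, ncp = hi) > target) {
    hi <- hi * 2
    if (hi > 1e8) stop("noncentrality inversion failed to bracket", call. = FALSE)
  }
  stats::uniroot(function(l) stats::pf(F, df1, df2, ncp = l) - target,
                 c(0, hi), tol = 1e-10)$root
}

#' Confidence interval for partial eta-squared
#'
#' Inverts the noncentral-F distribution: the bounds are the
#' noncentralities at which the observed F sits at the `(1+level)/2` and
#' `(1-level)/2` quantiles, converted to eta-squared via
#' `lambda / (lambda + df1 + df2 + 1)`. The lower bound is floored at 0
#' (and both bounds are 0 when F is small enough), giving the usual
#' one-sided behaviour near the null.
#'
#' @param F Observed F statistic.
#' @param df1,df2 Degrees of freedom.
#' @param level Confidence level in `(0, 1)`; effect-size intervals are
#'   conventionally reported at 0.90.
#' @return Numeric `c(lo, hi)`.
#' @examples
#' eta_sq_ci(5.50, 1, 226, 0.90)
#' @export
eta_sq_ci <- function(F, df1, df2, level = 0.90) {
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)", call. = FALSE)
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be positive", call. = FALSE)
  if (F < 0) stop("F must be non-negative", call. = FALSE)
  lam_lo <- invert_ncf(F, df1, df2, (1 + level) / 2)
  lam_hi <- invert_ncf(F, df1, df2, (1 - level) / 2)
  to_eta <- function(l) l / (l + df1 + df2 + 1)
  c(lo = to_eta(lam_lo), hi = to_eta(lam_hi))
}
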