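effect_size_result <- function(F, df1, df2, p, eta_sq, wilks_lambda = NULL,
                               ci_level = NULL, ci = NULL, ss = NULL) {
  structure(
    list(F = F, df1 = df1, df2 = df2, p = p, eta_sq = eta_sq,
         wilks_lambda = wilks_lambda, ci_level = ci_level, ci = ci, ss = ss),
    class = "effect_size_result"
  )
}

#' @export
print.effect_size_result <- function(x, ...) {
  cat(sprintf("F(%g, %g) = %.3f, p = %.4g, eta_sq = %.4f%s%s\n",
              x$df1, x$df2, x$F, x$p, x$eta_sq,
              if (!is.null(x$wilks_lambda))
                sprintf(", Wilks lambda = %.4f", x$wilks_lambda) else "",
              if (!is.null(x$ci))
                sprintf(", %g%% CI [%.4f, %.4f]", 100 * x$ci_level,
                        x$ci[1], x$ci[2]) else ""))
  invisible(x)
}

#' One-way between-groups ANOVA with partial eta-squared
#'
#' Standard between/within decomposition (via [stats::aov()]), returning F,
#' its degrees of freedom `(g - 1, N - g)`, the p-value, and partial
#' eta-squared with its noncentral-F confidence interval.
#'
#' @param groups List of numeric vectors, one per group (missing values
#'   dropped), or a single numeric vector with `labels` given.
#' @param labels Optional group labels when `groups` is a vector.
#' @param ci_level Confidence level for the eta-squared interval.
#' @return An `effect_size_result`; `ss` holds the between/within sums of
#'   squares.
#' @examples
#' oneway_anova(list(c(1, 2, 3), c(4, 5, 6)))  # F = 13.5, df = (1, 4)
#' @export
oneway_anova <- function(groups, labels = NULL, ci_level = 0.90) {
  if (!is.null(labels)) {
    groups <- split(groups, labels)
  }
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  n_g <- lengths(groups)
  if (any(n_g < 1L)) stop("every group needs at least one value", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), n_g))
  if (length(y) <= length(groups)) {
    stop("total n must exceed the number of groups", call. = FALSE)
  }
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  ssb <- tab["g", "Sum Sq"]
  ssw <- tab["Residuals", "Sum Sq"]
  if (ssw <= 0 && ssb <= 0) {
    stop("all values identical: F is undefined", call. = FALSE)
  }
  if (ssw <= 0) stop("zero within-group variance: F is undefined", call. = FALSE)
  F <- tab["g", "F value"]
  df1 <- tab["g", "Df"]
  df2 <- tab["Residuals", "Df"]
  effect_size_result(
    F = F, df1 = df1, df2 = df2, p = tab["g", "Pr(>F)"],
    eta_sq = partial_eta_sq(F, df1, df2),
    ci_level = ci_level, ci = eta_sq_ci(F, df1, df2, ci_level),
    ss = c(between = ssb, within = ssw)
  )
}

#' One-way MANOVA via Wilks lambda
#'
#' Computes the hypothesis (H) and error (E) cross-product matrices of a
#' between-groups multivariate design, Wilks `lambda = det(E) / det(E + H)`,
#' Rao's F approximation with its degrees of freedom, and the multivariate
#' effect size `eta_sq = 1 - lambda^(1/s)`. With a single outcome this
#' reduces exactly to the one-way ANOVA F. Within-subject (repeated
#' measures) factors are handled upstream by the multivariate approach:
#' pass [difference_scores()] for a time-by-group interaction, or
#' per-subject wave means for a group main effect.
#'
#' @param Y Numeric matrix or data frame, cases in rows, outcomes in
#'   columns.
#' @param groups Group label per case (2 or more levels).
#' @return An `effect_size_result` with `wilks_lambda` set; `ss` holds the
#'   `E` and `H` matrices.
#' @export
wilks_manova <- function(Y, groups) {
  Y <- as.matrix(Y)
  groups <- factor(groups)
  if (nrow(Y) != length(groups)) stop("Y and groups differ in length", call. = FALSE)
  keep <- stats::complete.cases(Y) & !is.na(groups)
  Y <- Y[keep, , drop = FALSE]
  groups <- droplevels(groups[keep])
  g <- nlevels(groups)
  if (g < 2L) stop("need at least two groups", call. = FALSE)
  n <- nrow(Y)
  p <- ncol(Y)
  if (n - g < p) stop("too few cases for the number of outcomes", call. = FALSE)

  grand <- colMeans(Y)
  H <- matrix(0, p, p)
  E <- matrix(0, p, p)
  for (lev in levels(groups)) {
    Yg <- Y[groups == lev, , drop = FALSE]
    mg <- colMeans(Yg)
    H <- H + nrow(Yg) * tcrossprod(mg - grand)
    E <- E + crossprod(sweep(Yg, 2, mg))
  }
  det_E <- det(E)
  if (det_E <= 0 || !is.finite(det_E)) {
    stop("singular error matrix: use fewer outcomes or more cases", call. = FALSE)
  }
  lambda <- det_E / det(E + H)

  # Rao's F approximation
  q <- g - 1
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  w <- (n - g) + q - (p + q + 1) / 2
  df1 <- p * q
  df2 <- w * s - (p * q - 2) / 2
  lam_s <- lambda^(1 / s)
  F <- (1 - lam_s) / lam_s * df2 / df1
  effect_size_result(
    F = F, df1 = df1, df2 = df2,
    p = stats::pf(F, df1, df2, lower.tail = FALSE),
    eta_sq = 1 - lam_s, wilks_lambda = lambda,
    ss = list(E = E, H = H)
  )
}

#' Per-subject difference scores across waves
#'
#' Builds the case-by-(outcome x contrast) matrix of successive wave
#' differences used by the multivariate approach to repeated measures: a
#' group test on these scores is the time-by-group interaction test.
#'
#' @param waves List of numeric matrices with identical dimensions and row
#'   ids (cases x outcomes, one per wave).
#' @return Matrix of `waves[[t+1]] - waves[[t]]` blocks, columns named
#'   `<outcome>_d<t>`.
#' @export
difference_scores <- function(waves) {
  if (length(waves) < 2L) stop("need at least two waves", call. = FALSE)
  waves <- lapply(waves, as.matrix)
  dims <- vapply(waves, dim, integer(2))
  if (length(unique(dims[1, ])) > 1L || length(unique(dims[2, ])) > 1L) {
    stop("waves must share dimensions", call. = FALSE)
  }
  out <- do.call(cbind, lapply(seq_len(length(waves) - 1L), function(t) {
    d <- waves[[t + 1L]] - waves[[t]]
    colnames(d) <- paste0(colnames(d) %||% paste0("y", seq_len(ncol(d))),
                          "_d", t)
    d
  }))
  out
}
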