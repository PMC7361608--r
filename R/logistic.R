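#' Binary logistic regression with odds ratios
#'
#' Maximum-likelihood fit via iteratively reweighted least squares
#' ([stats::glm()] with binomial link, convergence tolerance 1e-8), Wald
#' standard errors from the inverse information matrix, odds ratios
#' `exp(B)` with Wald confidence intervals computed from the unrounded
#' coefficients, the model likelihood-ratio chi-square against the
#' intercept-only model, and the classification rate at the 0.5
#' probability cutoff.
#'
#' @param X Numeric matrix or data frame of predictors (no intercept
#'   column; one is added).
#' @param y Binary outcome: 0/1, logical, or a two-level factor.
#' @param ci_level Confidence level for the odds-ratio intervals.
#' @return A `logistic_result`: `coefficients` data frame (`term`, `B`,
#'   `SE`, `z`, `p`, `OR`, `or_lo`, `or_hi`), `model_chi_sq`
#'   (`statistic`, `df`, `p`), `pct_correct`, `n`, `fit` (the glm object).
#' @export
logistic_fit <- function(X, y, ci_level = 0.95) {
  X <- as.data.frame(X)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary", call. = FALSE)
  if (length(unique(y)) < 2L) stop("y must contain both classes", call. = FALSE)
  if (nrow(X) != length(y)) stop("X and y differ in length", call. = FALSE)
  dat <- data.frame(X, .y = y, check.names = FALSE)
  # separation and convergence are diagnosed explicitly below, so glm.fit's
  # corresponding warnings are muffled
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) stop("IRLS did not converge", call. = FALSE)
  mu <- stats::fitted(fit)
  if (any(mu < 1e-8 | mu > 1 - 1e-8)) {
    co <- stats::coef(fit)[-1]
    worst <- names(co)[which.max(abs(co))]
    stop(sprintf("(quasi-)perfect separation detected (predictor '%s')", worst),
         call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  coefs <- data.frame(
    term = rownames(sm),
    B = sm[, "Estimate"],
    SE = sm[, "Std. Error"],
    z = sm[, "z value"],
    p = sm[, "Pr(>|z|)"],
    OR = exp(sm[, "Estimate"]),
    or_lo = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
    or_hi = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  lr <- fit$null.deviance - fit$deviance
  lr_df <- fit$df.null - fit$df.residual
  pred <- as.integer(mu >= 0.5)
  structure(
    list(coefficients = coefs,
         model_chi_sq = list(statistic = lr, df = lr_df,
                             p = stats::pchisq(lr, lr_df, lower.tail = FALSE)),
         pct_correct = 100 * mean(pred == y),
         n = length(y),
         fit = fit),
    class = "logistic_result"
  )
}

#' @export
print.logistic_result <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic regression (n = %d): model X2(%d) = %.2f, p = %.4g, %.1f%% correct\n",
              x$n, x$model_chi_sq$df, x$model_chi_sq$statistic,
              x$model_chi_sq$p, x$pct_correct))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}
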