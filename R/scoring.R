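#' Cronbach's alpha
#'
#' Internal-consistency reliability `k/(k-1) * (1 - sum(item variances) /
#' var(total score))`, computed over complete cases with sample (n-1)
#' variances.
#'
#' @param x Numeric matrix or data frame, one column per item.
#' @return List with `alpha`, `n_items`, `n_complete`.
#' @examples
#' v <- rnorm(50)
#' cronbach_alpha(cbind(v, v))$alpha  # parallel items: 1
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) {
    stop("alpha is undefined for fewer than 2 items", call. = FALSE)
  }
  cc <- stats::complete.cases(x)
  x <- x[cc, , drop = FALSE]
  if (nrow(x) < 2L) {
    stop("alpha needs at least 2 complete cases", call. = FALSE)
  }
  total_var <- stats::var(rowSums(x))
  if (total_var <= 0) {
    stop("alpha is undefined: total-score variance is zero", call. = FALSE)
  }
  k <- ncol(x)
  item_var <- sum(apply(x, 2, stats::var))
  list(alpha = k / (k - 1) * (1 - item_var / total_var),
       n_items = k, n_complete = nrow(x))
}

#' Score a multi-item scale
#'
#' Per-participant mean over the non-missing responses to the listed items,
#' plus Cronbach's alpha over complete cases — the standard way survey
#' batteries (e.g. a three-item behavioural-compliance scale) are scored.
#' All items must share one Likert scale.
#'
#' @param matrix A [response_matrix()].
#' @param item_ids Two or more item ids to score.
#' @param scale_name Name for the resulting scale.
#' @return An object of class `scale_score`: `scale_name`,
#'   `per_participant_mean` (named numeric, `NA` when a participant answered
#'   no item), `alpha`, `n_items`, `n_complete`.
#' @export
score_scale <- function(matrix, item_ids, scale_name) {
  stopifnot(inherits(matrix, "response_matrix"))
  sub <- subset_items(matrix, item_ids)
  if (length(item_ids) < 2L) {
    stop("a scale needs at least 2 items (alpha undefined otherwise)",
         call. = FALSE)
  }
  scales <- lapply(sub$items, `[[`, "scale")
  mins <- vapply(scales, `[[`, integer(1), "min")
  maxs <- vapply(scales, `[[`, integer(1), "max")
  if (length(unique(mins)) > 1L || length(unique(maxs)) > 1L) {
    stop("all scored items must share one Likert scale", call. = FALSE)
  }
  means <- rowMeans(sub$values, na.rm = TRUE)
  means[is.nan(means)] <- NA_real_
  a <- cronbach_alpha(sub$values)
  structure(
    list(scale_name = scale_name, per_participant_mean = means,
         alpha = a$alpha, n_items = a$n_items, n_complete = a$n_complete),
    class = "scale_score"
  )
}

#' @export
print.scale_score <- function(x, ...) {
  cat(sprintf("<scale_score '%s': %d items, alpha = %.3f (%d complete cases)>\n",
              x$scale_name, x$n_items, x$alpha, x$n_complete))
  invisible(x)
}

#' Mean, sample SD and n
#'
#' @param values Numeric vector; missing values are dropped.
#' @return List with `mean`, `sd` (n-1 denominator; 0 for a single value)
#'   and `n` (non-missing count).
#' @export
describe <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values to describe", call. = FALSE)
  s <- if (length(values) == 1L) 0 else stats::sd(values)
  list(mean = mean(values), sd = s, n = length(values))
}
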