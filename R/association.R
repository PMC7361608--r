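#' Pearson chi-square test of independence
#'
#' `sum((O - E)^2 / E)` with expected counts from the margin products and
#' `df = (r - 1)(c - 1)`; no continuity correction by default (the
#' large-sample convention).
#'
#' @param table An `r x c` count table (matrix or `table`).
#' @param correct Apply Yates continuity correction (2x2 only).
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @examples
#' chi_square_independence(rbind(c(10, 0), c(0, 10)))  # X2 = 20, df = 1
#' @export
chi_square_independence <- function(table, correct = FALSE) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), expected = ht$expected)
}

#' Pearson correlation with a two-sided t test
#'
#' @param x,y Numeric vectors of equal length (pairwise-complete cases
#'   used), both non-constant, at least 3 pairs.
#' @return List with `r`, `n`, `p` (two-sided, t transform on n-2 df).
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), n = length(x), p = unname(ht$p.value))
}
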