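#' Dice similarity coefficient
#'
#' Overlap between two binary masks, `2|A n B| / (|A| + |B|)`, ranging from 0
#' (disjoint) to 1 (identical). Two empty masks agree perfectly on absence and
#' score 1 by convention.
#'
#' @param a,b Binary matrices on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks must share the same grid")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean difference) and limits of agreement between two paired
#' measurement series. The limits are `bias +/- 2 SD` of the differences
#' (2 rather than 1.96, matching common cardiac-MR reporting practice).
#'
#' @param x,y Paired numeric vectors (e.g. automatic and reference T1, ms).
#' @return List: `bias`, `sd` (SD of differences, sample convention), `loa`
#'   (`c(lower, upper)`), `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s, loa = c(lower = bias - 2 * s, upper = bias + 2 * s),
       n = length(x))
}

#' Pearson correlation with zero-intercept regression slope
#'
#' The standard Pearson coefficient together with the slope of the
#' least-squares line through the origin (`y = slope * x`,
#' `slope = sum(xy) / sum(x^2)`), the form used when two methods measuring
#' the same physical quantity are compared.
#'
#' @param x,y Paired numeric vectors, `n >= 3`, non-degenerate variance.
#' @return List: `r`, `slope`, `n`.
#' @export
corr_with_origin_slope <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in input")
  list(r = stats::cor(x, y), slope = sum(x * y) / sum(x^2), n = length(x))
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation between two raters (e.g. automatic vs expert T1 readings),
#' with the F-distribution-based 95% confidence interval. Computed from the
#' two-way ANOVA mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#'
#' @param x,y Paired ratings of the same `n >= 5` subjects by two raters.
#' @param conf Confidence level (default 0.95).
#' @return List: `icc`, `ci` (`c(lower, upper)`), `n`.
#' @export
icc <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 5L) stop("need at least 5 paired ratings")
  ratings <- cbind(x, y)
  k <- 2L
  if (stats::var(as.vector(ratings)) == 0) {
    stop("degenerate input: all ratings identical, ICC undefined")
  }
  row_means <- rowMeans(ratings)
  col_means <- colMeans(ratings)
  grand <- mean(ratings)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- sum((ratings - outer(row_means, rep(1, k)) -
                   outer(rep(1, n), col_means) + grand)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc_val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # McGraw & Wong F-based interval for ICC(A,1)
  a <- k * icc_val / (n * (1 - icc_val))
  b <- 1 + k * icc_val * (n - 1) / (n * (1 - icc_val))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  alpha <- 1 - conf
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc_val, ci = c(lower = lower, upper = upper), n = n)
}
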