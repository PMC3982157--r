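#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (>= 3) with nonzero variance.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y")
  stats::cor(x, y, method = "pearson")
}

#' One-tailed significance of a Pearson correlation
#'
#' Given the correlation value `r` and the sample size `n`, computes
#' `t = r * sqrt((n - 2) / (1 - r^2))` and the one-tailed probability
#' `P(T >= |t|)` under Student's t with `n - 2` degrees of freedom, reported
#' in the direction of the observed sign.
#'
#' @param r correlation with `|r| < 1`.
#' @param n sample size (number of points), `n >= 3`.
#' @return one-tailed p in `(0, 0.5]`.
#' @export
one_tailed_p <- function(r, n) {
  if (n < 3L) stop("n must be >= 3")
  if (abs(r) >= 1)
    stop("|r| must be < 1 (perfect correlation: p underflows to 0)")
  t <- abs(r) * sqrt((n - 2) / (1 - r^2))
  pt(t, df = n - 2, lower.tail = FALSE)
}

#' Correlate bin ordinal with bin mean disorder
#'
#' Takes the site-count bin table from [bin_by_site_count()], uses the bin
#' ordinal (0, 1, ..., k) as x and the bin mean disorder fraction as y over
#' the populated bins, and returns the Pearson coefficient with its
#' one-tailed t significance.
#'
#' @param bins data frame from [bin_by_site_count()].
#' @return list of class `correlation_result`: `r`, `n`, `t`,
#'   `p_one_tailed`, `direction`.
#' @export
correlate_bins <- function(bins) {
  use <- bins$n_proteins > 0L & !is.na(bins$mean_disorder)
  if (sum(use) < 3L) stop("need at least 3 populated bins")
  x <- bins$bin_index[use]
  y <- bins$mean_disorder[use]
  r <- pearson_r(x, y)
  n <- length(x)
  # perfect correlation: t diverges and the one-tailed p underflows to 0
  t <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else one_tailed_p(r, n)
  structure(list(r = r, n = n, t = t, p_one_tailed = p,
                 direction = sign(r)),
            class = "correlation_result")
}
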