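#' Nonparanormal (truncated empirical-CDF) gaussianization
#'
#' Transforms every gene column to a Gaussian score: ranks divided by n are
#' truncated to `[delta_n, 1 - delta_n]` with
#' `delta_n = 1 / (4 n^{1/4} sqrt(pi log n))`, mapped through the standard
#' normal quantile function, and divided by the column's sample standard
#' deviation so every output column has unit standard deviation. The
#' transform depends only on ranks, so it is invariant to monotone
#' distortions of the marginals and idempotent up to this rescaling.
#'
#' @param x samples x genes numeric matrix, no missing values, at least 3
#'   rows. Ties get average ranks.
#' @return matrix of the same dimensions and dimnames.
#' @export
npn_transform <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("npn_transform needs at least 3 samples")
  if (anyNA(x)) stop("npn_transform does not accept missing values")
  const <- apply(x, 2, function(col) max(col) == min(col))
  if (any(const))
    stop("constant column(s): ",
         paste(head(colnames(x)[const], 5), collapse = ", "),
         " (ranks undefined up to ties)")
  delta <- 1 / (4 * n^0.25 * sqrt(pi * log(n)))
  out <- apply(x, 2, function(col) {
    u <- rank(col, ties.method = "average") / n
    z <- qnorm(pmin(pmax(u, delta), 1 - delta))
    z / sd(z)
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Jarque-Bera normality test
#'
#' Moment-based test of normality:
#' `JB = (n/6) (skew^2 + (kurt - 3)^2 / 4)` with sample skewness
#' `m3 / m2^{3/2}` and kurtosis `m4 / m2^2` (central moments with 1/n
#' normalization); the p-value comes from the chi-square distribution with
#' 2 degrees of freedom.
#'
#' @param x numeric vector, length at least 3, nonzero variance.
#' @return list with `statistic` and `p.value`.
#' @export
jarque_bera <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("jarque_bera needs at least 3 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("jarque_bera: zero variance")
  skew <- mean((x - m)^3) / m2^1.5
  kurt <- mean((x - m)^4) / m2^2
  stat <- n / 6 * (skew^2 + (kurt - 3)^2 / 4)
  list(statistic = stat, p.value = pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Filter to normally distributed genes
#'
#' Retains exactly the gene columns whose Jarque-Bera p-value exceeds
#' `alpha`, preserving column order.
#'
#' @param x samples x genes matrix.
#' @param alpha significance level in \[0, 1); a gene is kept iff its JB
#'   p-value is greater than `alpha` (so `alpha = 0` keeps everything).
#' @return list with `x` (the filtered matrix) and `report` (data frame:
#'   gene_id, jb_stat, p_value, kept).
#' @export
filter_normal <- function(x, alpha = 0.05) {
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  x <- as.matrix(x)
  jb <- apply(x, 2, jarque_bera)
  stat <- vapply(jb, `[[`, numeric(1), "statistic")
  pval <- vapply(jb, `[[`, numeric(1), "p.value")
  # alpha = 0 disables the filter (p-values can underflow to exactly 0)
  keep <- if (alpha == 0) rep(TRUE, ncol(x)) else pval > alpha
  if (!any(keep))
    stop("no gene passes the Jarque-Bera filter at alpha = ", alpha,
         "; consider a larger alpha or gaussianize with npn_transform first")
  report <- data.frame(gene_id = colnames(x), jb_stat = unname(stat),
                       p_value = unname(pval), kept = unname(keep),
                       stringsAsFactors = FALSE)
  list(x = x[, keep, drop = FALSE], report = report)
}
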