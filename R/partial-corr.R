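# Partial correlation by residualization.

#' Partial correlation of two variables given covariates
#'
#' Both variables are residualized on an intercept plus the covariates by
#' ordinary least squares; the partial correlation is the Pearson
#' correlation of the two residual vectors. The two-sided p-value uses the
#' t transform with n - 2 - k degrees of freedom (k covariates). With no
#' covariates this reduces to the plain Pearson correlation.
#'
#' @param x,y numeric vectors of equal length n.
#' @param covariates n x k numeric matrix, or NULL.
#' @return list: `r`, `p`, `df`, `n`. When either residual has zero
#'   variance, `r` and `p` are `NA` with a warning.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite")
  }
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 2) stop("need n > k + 2 observations")
  Z <- cbind(rep(1, n), if (k) as.matrix(covariates))
  qz <- qr(Z)
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12) {
    warning("zero residual variance: partial correlation undefined")
    return(list(r = NA_real_, p = NA_real_, df = n - 2L - k, n = n))
  }
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - 2L - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(r = r, p = p, df = df, n = n)
}
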