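#' Fisher z-transform of a correlation coefficient
#'
#' Computes \code{atanh(rho)} after clipping \code{|rho|} to
#' \code{1 - 1e-10}, so the result is always finite. Used throughout the
#' package to map correlation-based statistics onto an approximately normal
#' scale before group-level inference.
#'
#' @param rho Numeric vector of correlation coefficients in \code{[-1, 1]}.
#' @return Numeric vector of Fisher z values; \code{NA} propagates.
#' @export
fisher_z <- function(rho) {
  atanh(pmin(pmax(rho, -1 + 1e-10), 1 - 1e-10))
}

# Spearman rank correlation with average ranks (Pearson on ranks).
# stats::cor(method = "spearman") implements exactly this; wrapped so the
# tie convention is set in one place.
spearman_rho <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

# z-score a vector; errors on zero spread unless allow_constant.
zscore_vec <- function(x, label = "predictor") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score constant ", label, call. = FALSE)
  }
  (x - mean(x)) / s
}

# Draw n samples from N(0, sigma) given a covariance matrix, via Cholesky.
rmvnorm_chol <- function(n, sigma) {
  p <- nrow(sigma)
  R <- chol(sigma)
  matrix(stats::rnorm(n * p), n, p) %*% R
}

`%||%` <- function(a, b) if (is.null(a)) b else a
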