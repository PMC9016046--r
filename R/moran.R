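#' Moran's I with k-nearest-neighbor weights
#'
#' Global spatial autocorrelation of a variable (typically model
#' residuals) using row-standardized k-nearest-neighbor weights:
#' `I = (n / S0) * sum_ij w_ij (r_i - rbar)(r_j - rbar) / sum_i
#' (r_i - rbar)^2`. The expectation under spatial randomness is
#' `-1 / (n - 1)`.
#'
#' @param residuals numeric vector.
#' @param x,y coordinates of the observations.
#' @param k number of nearest neighbors (default 8); distance ties beyond
#'   the k-th neighbor are broken by order of appearance.
#' @return List with `I`, `expectation`, `n`, `k`. `I` is `NA` (with a
#'   warning) when the residuals have zero variance.
#' @export
morans_i <- function(residuals, x, y, k = 8) {
  n <- length(residuals)
  if (n < 10) stop("Moran's I needs at least 10 observations")
  z <- residuals - mean(residuals)
  denom <- sum(z^2)
  if (denom == 0) {
    warning("zero residual variance: Moran's I undefined")
    return(list(I = NA_real_, expectation = -1 / (n - 1), n = n, k = k))
  }
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  num <- 0
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[seq_len(k)]
    num <- num + sum(z[nb]) * z[i] / k   # row-standardized weights 1/k
  }
  # row-standardized: S0 = n, so the n/S0 prefactor is 1
  list(I = num / denom, expectation = -1 / (n - 1), n = n, k = k)
}
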