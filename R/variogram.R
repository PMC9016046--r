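#' Variogram model families
#' @return Character vector of the five supported family names, in
#'   tie-break order.
#' @export
variogram_families <- function() {
  c("Spherical", "Exponential", "Gaussian", "Matern", "Stein")
}

#' Evaluate a variogram model
#'
#' `gamma(h) = nugget + psill * f(h / range)` for `h > 0`, `gamma(0) = 0`.
#' Families: Spherical (`1.5u - 0.5u^3`, capped at 1), Exponential
#' (`1 - exp(-u)`, `range` is the distance parameter), Gaussian
#' (`1 - exp(-u^2)`), Matern in the Bessel-K form
#' (`1 - 2^(1-k)/Gamma(k) * u^k * K_k(u)`), and Stein's Matern
#' parameterization (same form evaluated at `2*sqrt(k)*u`).
#'
#' @param h distances (vector or matrix, m).
#' @param family one of [variogram_families()].
#' @param nugget,psill,range_m model parameters (`nugget`, `psill >= 0`,
#'   `range_m > 0`).
#' @param kappa smoothness for Matern/Stein (> 0), ignored otherwise.
#' @return Semivariance values, same shape as `h`.
#' @export
variogram_model_value <- function(h, family, nugget, psill, range_m,
                                  kappa = 0.5) {
  u <- h / range_m
  f <- switch(family,
    Spherical = ifelse(u < 1, 1.5 * u - 0.5 * u^3, 1),
    Exponential = 1 - exp(-u),
    Gaussian = 1 - exp(-u^2),
    Matern = .matern_f(u, kappa),
    Stein = .matern_f(2 * sqrt(kappa) * u, kappa),
    stop("unknown variogram family: ", family))
  g <- nugget + psill * f
  g[h == 0] <- 0
  g
}

.matern_f <- function(u, kappa) {
  out <- u
  small <- u < 1e-10
  big <- u > 600                       # besselK underflows; f -> 1
  mid <- !small & !big
  out[small] <- 0
  out[big] <- 1
  if (any(mid)) {
    um <- u[mid]
    out[mid] <- 1 - (2^(1 - kappa) / gamma(kappa)) * um^kappa *
      besselK(um, kappa)
  }
  pmin(pmax(out, 0), 1)
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Bins all point pairs up to `cutoff` into `n_bins` equal-width lag bins
#' and computes `gamma_j = mean(0.5 * (z_i - z_k)^2)` per bin. Empty bins
#' are dropped.
#'
#' @param x,y point coordinates (m).
#' @param values field values at the points.
#' @param n_bins number of lag bins (default 15).
#' @param cutoff maximum lag distance; defaults to one third of the
#'   maximum inter-point distance.
#' @return data.frame of class `empirical_variogram` with columns `h`
#'   (bin center), `gamma`, `n` (pair count); the cutoff is attached as
#'   attribute `"cutoff"`.
#' @export
empirical_semivariogram <- function(x, y, values, n_bins = 15,
                                    cutoff = NULL) {
  if (length(x) < 2) stop("need at least 2 points")
  d <- stats::dist(cbind(x, y))
  dmax <- max(d)
  if (dmax == 0) stop("degenerate geometry: all points coincident")
  if (is.null(cutoff)) cutoff <- dmax / 3
  if (cutoff <= 0) stop("cutoff must be positive")
  g <- 0.5 * stats::dist(values)^2
  keep <- d <= cutoff & d > 0
  dk <- d[keep]; gk <- g[keep]
  bin <- pmin(floor(dk / cutoff * n_bins) + 1, n_bins)
  n_j <- tabulate(bin, n_bins)
  gamma_j <- rep(NA_real_, n_bins)
  sums <- tapply(gk, factor(bin, levels = seq_len(n_bins)), sum)
  gamma_j <- as.numeric(sums) / n_j
  centers <- (seq_len(n_bins) - 0.5) * cutoff / n_bins
  out <- data.frame(h = centers, gamma = gamma_j, n = n_j)
  out <- out[out$n > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

#' Fit a variogram model to an empirical semivariogram
#'
#' Weighted least squares (weights `N_j / h_j^2`) over the five model
#' families, with a kappa search grid for Matern and Stein. The family and
#' parameters with the smallest weighted SSE win; ties are broken by the
#' order of [variogram_families()].
#'
#' @param emp an [empirical_semivariogram()] (needs >= 4 bins).
#' @param families subset of [variogram_families()] to try.
#' @param kappa_grid smoothness values searched for Matern/Stein.
#' @return List of class `variogram_model`: `family`, `nugget`, `psill`,
#'   `range_m`, `kappa` (`NA` for families without smoothness),
#'   `fit_error` (weighted SSE) and `candidates` (per-family best SSE).
#' @export
fit_variogram <- function(emp, families = variogram_families(),
                          kappa_grid = c(0.05, 0.1, 0.2, 0.3, 0.5, 0.7, 1,
                                         1.5, 2, 3, 5, 10)) {
  if (nrow(emp) < 4)
    stop("need at least 4 non-empty lag bins to fit a variogram")
  h <- emp$h; g <- emp$gamma; w <- emp$n / emp$h^2
  cutoff <- attr(emp, "cutoff")
  if (is.null(cutoff)) cutoff <- max(h)
  sill0 <- mean(utils::tail(g, 3))
  nug0 <- min(g[1], sill0)
  obj <- function(par, family, kappa) {
    gm <- variogram_model_value(h, family, par[1], par[2], par[3], kappa)
    sum(w * (g - gm)^2)
  }
  fit_one <- function(family, kappa) {
    starts <- expand.grid(
      nugget = unique(c(nug0, 0)),
      psill = max(sill0 - nug0, 1e-8 + 0.1 * sill0),
      range = cutoff * c(0.1, 0.25, 0.5, 1))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      res <- tryCatch(
        stats::nlminb(as.numeric(starts[s, ]), obj, family = family,
                      kappa = kappa,
                      lower = c(0, 0, cutoff * 1e-4),
                      upper = c(Inf, Inf, cutoff * 100)),
        error = function(e) NULL)
      if (!is.null(res) && (is.null(best) || res$objective < best$objective))
        best <- res
    }
    best
  }
  results <- list()
  for (fam in families) {
    kappas <- if (fam %in% c("Matern", "Stein")) kappa_grid else NA_real_
    fam_best <- NULL
    for (k in kappas) {
      r <- fit_one(fam, if (is.na(k)) 0.5 else k)
      if (!is.null(r) &&
          (is.null(fam_best) || r$objective < fam_best$objective))
        fam_best <- c(r, list(kappa = k))
    }
    if (is.null(fam_best)) next
    results[[fam]] <- fam_best
  }
  if (!length(results)) stop("variogram fit failed for all families")
  sses <- vapply(results, function(r) r$objective, 0)
  # near-identical SSEs (several families alias each other exactly, e.g.
  # Exponential = Matern kappa 0.5) count as ties, broken by family order
  tol <- 1e-9 * (sum(w * g^2) + min(sses))
  best_fam <- names(results)[which(sses <= min(sses) + tol)[1]]
  b <- results[[best_fam]]
  structure(
    list(family = best_fam, nugget = b$par[1], psill = b$par[2],
         range_m = b$par[3], kappa = b$kappa, fit_error = b$objective,
         candidates = sses),
    class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "variogram_model: %s (nugget %.4g, partial sill %.4g, range %.4g m%s)\n",
    x$family, x$nugget, x$psill, x$range_m,
    if (!is.na(x$kappa)) sprintf(", kappa %.3g", x$kappa) else ""))
  cat(sprintf("  weighted SSE: %.4g\n", x$fit_error))
  invisible(x)
}

#' Effective range of a variogram model
#'
#' The lag at which the model semivariance reaches 95% of its total sill
#' (`nugget + psill`); for the spherical family this is slightly below the
#' range parameter, for unbounded families it is where the curve flattens.
#'
#' @param model a `variogram_model`.
#' @param level fraction of the sill (default 0.95).
#' @return Effective range in m.
#' @export
effective_range <- function(model, level = 0.95) {
  target <- model$nugget + level * model$psill
  f <- function(h) variogram_model_value(h, model$family, model$nugget,
                                         model$psill, model$range_m,
                                         model$kappa) - target
  upper <- model$range_m
  while (f(upper) < 0 && upper < model$range_m * 1e4) upper <- upper * 2
  stats::uniroot(f, c(model$range_m * 1e-6, upper))$root
}
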