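#' Prediction grid covering a set of points
#'
#' An empty [raster_grid()] whose extent is the bounding box of the points
#' padded by one cell, with the requested resolution (100 m by default,
#' the resolution used for the interpolated change maps).
#'
#' @param x,y point coordinates (m).
#' @param cellsize cell size (m).
#' @return A `raster_grid` of `NA` values.
#' @export
kriging_grid <- function(x, y, cellsize = 100) {
  xll <- floor(min(x) / cellsize - 1) * cellsize
  yll <- floor(min(y) / cellsize - 1) * cellsize
  ncols <- ceiling((max(x) - xll) / cellsize) + 1
  nrows <- ceiling((max(y) - yll) / cellsize) + 1
  raster_grid(matrix(NA_real_, nrows, ncols), xll = xll, yll = yll,
              cellsize = cellsize)
}

#' Ordinary kriging weights for one target location
#'
#' Solves the ordinary kriging system (semivariance matrix augmented with
#' the unbiasedness constraint) for a single prediction point. Mainly
#' useful for inspection and testing; [ordinary_kriging()] factorizes the
#' system once for a whole grid.
#'
#' @param x,y data point coordinates.
#' @param model a `variogram_model`.
#' @param x0,y0 target location.
#' @return List with `weights` (summing to 1) and `lagrange`.
#' @export
kriging_weights <- function(x, y, model, x0, y0) {
  A <- .krige_lhs(x, y, model)
  d0 <- sqrt((x - x0)^2 + (y - y0)^2)
  b <- c(variogram_model_value(d0, model$family, model$nugget, model$psill,
                               model$range_m, model$kappa), 1)
  sol <- solve(A, b)
  n <- length(x)
  list(weights = sol[seq_len(n)], lagrange = sol[n + 1])
}

.krige_lhs <- function(x, y, model) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  G <- variogram_model_value(d, model$family, model$nugget, model$psill,
                             model$range_m, model$kappa)
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  A
}

#' Ordinary kriging onto a raster grid
#'
#' Interpolates point values at the cell centres of `grid` using the
#' fitted variogram model. Duplicate locations are averaged (with a
#' warning). With a zero nugget the prediction at a data location
#' reproduces the observed value. When the data are constant the constant
#' is returned everywhere with a warning (the variogram is degenerate).
#'
#' @param x,y,values data points.
#' @param model a `variogram_model` from [fit_variogram()].
#' @param grid a [raster_grid()] template (values ignored), e.g. from
#'   [kriging_grid()].
#' @param max_neighbors number of nearest data points used per cell; by
#'   default all points when `n <= 2000`, else the 64 nearest.
#' @return A `raster_grid` of predictions.
#' @export
ordinary_kriging <- function(x, y, values, model, grid,
                             max_neighbors = NULL) {
  stopifnot(length(x) == length(y), length(x) == length(values))
  if (length(x) < 2) stop("ordinary kriging needs at least 2 data points")
  key <- paste(x, y)
  if (anyDuplicated(key)) {
    warning("duplicate data locations averaged before kriging")
    agg <- tapply(values, key, mean)
    first <- !duplicated(key)
    ord <- key[first]
    x <- x[first]; y <- y[first]
    values <- as.numeric(agg[ord])
  }
  n <- length(x)
  cc <- raster_cell_centers(grid)
  gx <- rep(cc$x, each = grid$nrows)
  gy <- rep(cc$y, times = grid$ncols)
  pred <- numeric(length(gx))
  if (stats::sd(values) == 0) {
    warning("constant field: kriging skipped, constant surface returned")
    out <- grid
    out$values <- matrix(values[1], grid$nrows, grid$ncols)
    return(out)
  }
  if (is.null(max_neighbors)) max_neighbors <- if (n <= 2000) n else 64
  if (max_neighbors >= n) {
    A <- .krige_lhs(x, y, model)
    dx <- outer(x, gx, "-"); dy <- outer(y, gy, "-")
    D0 <- sqrt(dx^2 + dy^2)
    B <- rbind(variogram_model_value(D0, model$family, model$nugget,
                                     model$psill, model$range_m,
                                     model$kappa),
               rep(1, length(gx)))
    W <- solve(A, B)
    pred <- as.numeric(crossprod(W[seq_len(n), , drop = FALSE], values))
  } else {
    for (i in seq_along(gx)) {
      d0 <- sqrt((x - gx[i])^2 + (y - gy[i])^2)
      nb <- order(d0)[seq_len(max_neighbors)]
      kw <- kriging_weights(x[nb], y[nb], model, gx[i], gy[i])
      pred[i] <- sum(kw$weights * values[nb])
    }
  }
  out <- grid
  out$values <- matrix(pred, grid$nrows, grid$ncols)
  out
}

#' Compare two interpolated change surfaces
#'
#' RMSE over all cells valid in both rasters, and trend congruence: the
#' percentage of valid cells where the two surfaces agree in sign (zero
#' counts as congruent only with zero).
#'
#' @param a,b `raster_grid`s on identical grids.
#' @return List with `rmse` and `trend_congruence_pct`.
#' @export
compare_patterns <- function(a, b) {
  if (a$nrows != b$nrows || a$ncols != b$ncols ||
      a$cellsize != b$cellsize || a$xll != b$xll || a$yll != b$yll)
    stop("dimension error: rasters are not on the same grid")
  va <- as.numeric(a$values); vb <- as.numeric(b$values)
  ok <- !is.na(va) & !is.na(vb)
  if (!any(ok)) stop("no jointly valid cells")
  rmse <- sqrt(mean((va[ok] - vb[ok])^2))
  cong <- 100 * mean(sign(va[ok]) == sign(vb[ok]))
  list(rmse = rmse, trend_congruence_pct = cong)
}

#' Variogram-fitted kriging surface of one change variable
#'
#' Convenience wrapper: empirical semivariogram, model fit over the five
#' families, and ordinary kriging onto a shared grid. Degenerate (constant
#' or near-constant) fields yield a constant surface and a `NULL` model.
#'
#' @param x,y,values per-plot change values at plot locations.
#' @param grid prediction grid; default [kriging_grid()] at 100 m.
#' @param n_bins,cutoff passed to [empirical_semivariogram()].
#' @return List with `model` (a `variogram_model` or `NULL`) and `surface`
#'   (a `raster_grid`).
#' @export
krige_change_surface <- function(x, y, values, grid = NULL, n_bins = 15,
                                 cutoff = NULL) {
  if (is.null(grid)) grid <- kriging_grid(x, y)
  if (stats::sd(values) == 0) {
    warning("constant change field: returning constant surface")
    out <- grid
    out$values <- matrix(values[1], grid$nrows, grid$ncols)
    return(list(model = NULL, surface = out))
  }
  emp <- empirical_semivariogram(x, y, values, n_bins = n_bins,
                                 cutoff = cutoff)
  model <- fit_variogram(emp)
  list(model = model,
       surface = ordinary_kriging(x, y, values, model, grid))
}
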