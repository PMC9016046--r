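#' Terrain indices on a 3 x 3 neighborhood
#'
#' Computes, per DEM cell: roughness (difference between the maximum and
#' minimum elevation of the cell and its eight neighbors), the Terrain
#' Ruggedness Index (mean absolute elevation difference between the cell
#' and its eight neighbors), the Topographic Position Index (cell elevation
#' minus the mean of its eight neighbors), and an eight-class cardinal
#' aspect derived from the steepest-descent direction of the central-
#' difference gradient. Border cells use the neighbors that exist; cells
#' with gradient magnitude below `flat_tol` are classed `"flat"`.
#'
#' @param dem a [raster_grid()] with at least 3 x 3 cells.
#' @param flat_tol slope threshold (m/m) below which a cell is flat.
#' @return List of three `raster_grid`s (`roughness`, `tri`, `tpi`, in m)
#'   and a character matrix `aspect_class` in DEM orientation.
#' @export
terrain_indices <- function(dem, flat_tol = 1e-6) {
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3)
    stop("terrain indices require a DEM of at least 3 x 3 cells")
  # stack the 8 shifted neighbor layers; outside-the-grid stays NA
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                 c(1, -1), c(1, 0), c(1, 1))
  nb <- array(NA_real_, dim = c(nr, nc, 8))
  for (k in seq_along(shifts)) {
    dr <- shifts[[k]][1]; dc <- shifts[[k]][2]
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    nb[rs - dr, cs - dc, k] <- z[rs, cs]
  }
  nb_min <- apply(nb, c(1, 2), min, na.rm = TRUE)
  nb_max <- apply(nb, c(1, 2), max, na.rm = TRUE)
  nb_mean <- apply(nb, c(1, 2), mean, na.rm = TRUE)
  absdiff <- abs(nb - array(z, dim = c(nr, nc, 8)))
  tri <- apply(absdiff, c(1, 2), mean, na.rm = TRUE)
  roughness <- pmax(nb_max, z) - pmin(nb_min, z)
  tpi <- z - nb_mean

  # central-difference gradient; one-sided at borders. Row 1 is north.
  cs <- dem$cellsize
  east <- cbind(z[, -1], z[, nc]); west <- cbind(z[, 1], z[, -nc])
  dx_den <- matrix(2 * cs, nr, nc); dx_den[, c(1, nc)] <- cs
  dzdx <- (east - west) / dx_den
  north <- rbind(z[1, ], z[-nr, ]); south <- rbind(z[-1, ], z[nr, ])
  dy_den <- matrix(2 * cs, nr, nc); dy_den[c(1, nr), ] <- cs
  dzdy <- (north - south) / dy_den
  slope <- sqrt(dzdx^2 + dzdy^2)
  # downslope (steepest descent) azimuth, clockwise from north
  azim <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  classes <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
  idx <- (floor((azim + 22.5) / 45) %% 8) + 1
  aspect <- matrix(classes[idx], nr, nc)
  aspect[slope < flat_tol] <- "flat"

  g <- function(v) raster_grid(v, xll = dem$xll, yll = dem$yll,
                               cellsize = dem$cellsize, nodata = dem$nodata)
  list(roughness = g(roughness), tri = g(tri), tpi = g(tpi),
       aspect_class = aspect)
}

#' Terrain attributes at plot locations
#'
#' Extracts roughness, TRI, TPI and aspect class from a DEM at each plot's
#' coordinates.
#'
#' @param dem a [raster_grid()].
#' @param plots plot table with `plot_id`, `x_m`, `y_m`.
#' @return data.frame with `plot_id`, `roughness`, `tri`, `tpi`,
#'   `aspect_class`.
#' @export
plot_terrain <- function(dem, plots) {
  ti <- terrain_indices(dem)
  col <- pmin(pmax(floor((plots$x_m - dem$xll) / dem$cellsize) + 1, 1),
              dem$ncols)
  row_s <- pmin(pmax(floor((plots$y_m - dem$yll) / dem$cellsize) + 1, 1),
                dem$nrows)
  row <- dem$nrows - row_s + 1
  ij <- cbind(row, col)
  data.frame(plot_id = plots$plot_id,
             roughness = ti$roughness$values[ij],
             tri = ti$tri$values[ij],
             tpi = ti$tpi$values[ij],
             aspect_class = ti$aspect_class[ij])
}
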