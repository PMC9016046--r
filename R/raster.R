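#' Rectangular raster grid
#'
#' Lightweight container for a regular raster: a numeric matrix ordered
#' north-to-south (row 1 is the northernmost row) and west-to-east, plus the
#' lower-left corner and cell size in metres. Cell values are interpreted at
#' cell centres.
#'
#' @param values numeric matrix, `nrows x ncols`, row 1 = northernmost row.
#' @param xll,yll coordinates (m) of the lower-left corner of the grid.
#' @param cellsize cell edge length in metres; must be positive.
#' @param nodata sentinel used for missing cells on disk (values are stored
#'   as `NA` in memory).
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xll = 0, yll = 0, cellsize = 10,
                        nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1 || cellsize <= 0)
    stop("cellsize must be a single positive number")
  structure(
    list(values = values, nrows = nrow(values), ncols = ncol(values),
         xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize), nodata = as.numeric(nodata)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d rows x %d cols, cellsize %g m\n",
              x$nrows, x$ncols, x$cellsize))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xll, x$xll + x$ncols * x$cellsize,
              x$yll, x$yll + x$nrows * x$cellsize))
  v <- x$values[!is.na(x$values)]
  if (length(v))
    cat(sprintf("  values: min %.3f, mean %.3f, max %.3f (%d NA)\n",
                min(v), mean(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' Cell-centre coordinates of a raster
#'
#' @param grid a [raster_grid()].
#' @return List with vectors `x` (west to east) and `y` (north to south,
#'   matching the row order of `grid$values`).
#' @export
raster_cell_centers <- function(grid) {
  cs <- grid$cellsize
  x <- grid$xll + (seq_len(grid$ncols) - 0.5) * cs
  y <- grid$yll + (grid$nrows - seq_len(grid$nrows) + 0.5) * cs
  list(x = x, y = y)
}

#' Extract raster values at point locations
#'
#' Nearest-cell lookup (the cell containing each point). Points outside the
#' extent are clamped to the border cell.
#'
#' @param grid a [raster_grid()].
#' @param x,y point coordinates in metres.
#' @return Numeric vector of cell values.
#' @export
raster_extract <- function(grid, x, y) {
  col <- floor((x - grid$xll) / grid$cellsize) + 1
  row_from_s <- floor((y - grid$yll) / grid$cellsize) + 1
  col <- pmin(pmax(col, 1), grid$ncols)
  row_from_s <- pmin(pmax(row_from_s, 1), grid$nrows)
  row <- grid$nrows - row_from_s + 1
  grid$values[cbind(row, col)]
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by `nrows` rows of
#' values ordered north to south. Nodata cells become `NA`.
#'
#' @param path file to read.
#' @return A [raster_grid()].
#' @export
read_raster_ascii <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2)
      stop("malformed raster header line: ", lines[i])
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  missing <- setdiff(need, names(hdr))
  if (length(missing))
    stop("raster header missing field(s): ", paste(missing, collapse = ", "))
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows)
    stop(sprintf("raster dimension error: expected %d data rows, found %d",
                 hdr$nrows, length(body)))
  vals <- t(vapply(body, function(l) {
    v <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    if (length(v) != hdr$ncols)
      stop(sprintf("raster dimension error: expected %d columns, found %d",
                   hdr$ncols, length(v)))
    v
  }, numeric(hdr$ncols), USE.NAMES = FALSE))
  if (hdr$ncols == 1) vals <- matrix(as.numeric(vals), ncol = 1)
  vals[vals == hdr$nodata_value] <- NA_real_
  raster_grid(vals, xll = hdr$xllcorner, yll = hdr$yllcorner,
              cellsize = hdr$cellsize, nodata = hdr$nodata_value)
}

#' Write an ESRI ASCII grid
#'
#' @param grid a [raster_grid()].
#' @param path output file; `NA` cells are written as the grid's nodata value.
#' @return `path`, invisibly.
#' @export
write_raster_ascii <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  hdr <- c(sprintf("ncols %d", grid$ncols),
           sprintf("nrows %d", grid$nrows),
           sprintf("xllcorner %.10g", grid$xll),
           sprintf("yllcorner %.10g", grid$yll),
           sprintf("cellsize %.10g", grid$cellsize),
           sprintf("NODATA_value %.10g", grid$nodata))
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata
  rows <- apply(vals, 1, function(r) paste(sprintf("%.8g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
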