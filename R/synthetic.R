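#' Species-trait table of the synthetic species pool
#'
#' Eight synthetic species loosely modeled on a calcareous Alpine mountain
#' landscape: spruce/fir/beech as late-seral dominants, larch/birch/rowan
#' as early-seral colonists, stone pine and sycamore maple as rare species.
#'
#' @return data.frame with `species_code`, `conifer`, `seral_class`.
#' @export
synthetic_species <- function() {
  data.frame(
    species_code = c("PIAB", "ABAL", "FASY", "LADE", "PICE", "BEPE",
                     "ACPS", "SOAU"),
    conifer = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    seral_class = c("late", "late", "late", "early", "rare", "early",
                    "rare", "early"),
    stringsAsFactors = FALSE)
}

#' Simulate a Gaussian random field with a known variogram
#'
#' Exact simulation by Cholesky factorization of the covariance matrix
#' implied by a variogram model (`cov(h) = sill - gamma(h)` plus a nugget
#' at h = 0). Intended for moderate point counts (n up to a few thousand).
#'
#' @param x,y point coordinates (m).
#' @param family variogram family, see [variogram_model_value()].
#' @param sill partial sill of the field.
#' @param range_m range parameter (m).
#' @param nugget nugget variance (white-noise component).
#' @param kappa smoothness (Matern/Stein only).
#' @return Numeric vector of field values (mean zero).
#' @export
simulate_gaussian_field <- function(x, y, family = "Exponential", sill = 1,
                                    range_m = 500, nugget = 0, kappa = 0.5) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  gam <- variogram_model_value(d, family, nugget = 0, psill = sill,
                               range_m = range_m, kappa = kappa)
  C <- sill - gam
  diag(C) <- sill + nugget + 1e-8 * sill
  L <- chol(C)
  as.numeric(crossprod(L, stats::rnorm(n)))
}

# bilinear interpolation of a coarse field (matrix, row 1 = north) onto
# arbitrary coordinates; used to upsample coarse-grid noise fields
.interp_field <- function(vals, xll, yll, cellsize, x, y) {
  nr <- nrow(vals); nc <- ncol(vals)
  gx <- (x - xll) / cellsize - 0.5
  gy <- (y - yll) / cellsize - 0.5
  cx <- pmin(pmax(gx, 0), nc - 1); cy <- pmin(pmax(gy, 0), nr - 1)
  i0 <- pmin(floor(cx), nc - 2); j0 <- pmin(floor(cy), nr - 2)
  fx <- cx - i0; fy <- cy - j0
  row0 <- nr - j0          # row index of the southern cell (1-based from N)
  v00 <- vals[cbind(row0, i0 + 1)]; v10 <- vals[cbind(row0, i0 + 2)]
  v01 <- vals[cbind(row0 - 1, i0 + 1)]; v11 <- vals[cbind(row0 - 1, i0 + 2)]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

#' Generate synthetic mountain terrain, soils and PNV
#'
#' Builds a 10 m DEM as a superposition of randomly placed smooth Gaussian
#' bumps rescaled exactly to `elev_range`, plus soil property fields (sand,
#' clay, effective depth) combining an elevation trend with spatially
#' correlated noise of known variogram, a four-class soil-type map, and an
#' elevation-banded potential-natural-vegetation map. All random fields and
#' their variogram parameters are recorded in `truth$field_variograms`.
#'
#' @param extent_m numeric length-2, landscape width and height (m);
#'   at least 1000 x 1000.
#' @param seed integer RNG seed; output is deterministic given the seed.
#' @param cellsize_m DEM resolution (default 10 m).
#' @param elev_range min and max elevation (m asl) of the rescaled DEM.
#' @param n_bumps number of Gaussian hills/valleys superposed.
#' @return A landscape bundle: list with `dem`, `sand`, `clay`, `depth`
#'   (raster_grids), `soil_type` (character matrix), `pnv` (character
#'   matrix of semicolon-joined dominant species), `extent_m`, and `truth`
#'   (partial [synthetic_truth()] carrying the field variogram record).
#' @export
generate_terrain <- function(extent_m = c(4000, 2400), seed = 1,
                             cellsize_m = 10, elev_range = c(603, 2713),
                             n_bumps = 40) {
  if (any(extent_m < 1000))
    stop("configuration error: extent must be at least 1 x 1 km")
  if (any(extent_m < cellsize_m))
    stop("configuration error: extent smaller than one DEM cell")
  set.seed(seed)
  nc <- round(extent_m[1] / cellsize_m)
  nr <- round(extent_m[2] / cellsize_m)
  cx <- (seq_len(nc) - 0.5) * cellsize_m
  cy <- (nr - seq_len(nr) + 0.5) * cellsize_m   # row 1 = north
  xg <- matrix(cx, nr, nc, byrow = TRUE)
  yg <- matrix(cy, nr, nc)
  z <- matrix(0, nr, nc)
  bx <- stats::runif(n_bumps, 0, extent_m[1])
  by <- stats::runif(n_bumps, 0, extent_m[2])
  bs <- stats::runif(n_bumps, 0.08, 0.35) * max(extent_m)
  ba <- stats::rnorm(n_bumps, 0, 1) * bs / max(extent_m) * 4
  for (k in seq_len(n_bumps))
    z <- z + ba[k] * exp(-((xg - bx[k])^2 + (yg - by[k])^2) / (2 * bs[k]^2))
  z <- elev_range[1] +
    (z - min(z)) / (max(z) - min(z)) * (elev_range[2] - elev_range[1])
  dem <- raster_grid(z, xll = 0, yll = 0, cellsize = cellsize_m)

  # soil noise: exact Gaussian fields on a coarse 100 m lattice, bilinearly
  # upsampled; the coarse-lattice variogram is what truth records
  coarse <- 100
  ncc <- max(round(extent_m[1] / coarse), 4)
  ncr <- max(round(extent_m[2] / coarse), 4)
  sx <- rep((seq_len(ncc) - 0.5) * coarse, each = ncr)
  sy <- rep((ncr - seq_len(ncr) + 0.5) * coarse, times = ncc)
  field_vgms <- list(
    sand = list(family = "Exponential", nugget = 0, sill = 64,
                range_m = 600),
    clay = list(family = "Exponential", nugget = 0, sill = 16,
                range_m = 600),
    depth = list(family = "Gaussian", nugget = 0, sill = 36,
                 range_m = 500),
    warm_mod = list(family = "Exponential", nugget = 0, sill = 4,
                    range_m = 250))
  noise <- lapply(field_vgms, function(v)
    matrix(simulate_gaussian_field(sx, sy, v$family, v$sill, v$range_m),
           ncr, ncc))
  up <- function(m) matrix(
    .interp_field(m, 0, 0, coarse, as.vector(t(xg)), as.vector(t(yg))),
    nr, nc, byrow = TRUE)
  relev <- (z - mean(z)) / stats::sd(z)
  sand <- pmin(pmax(45 + 5 * relev + up(noise$sand), 5), 90)
  clay <- pmin(pmax(20 - 3 * relev + up(noise$clay), 2), 60)
  clay <- pmin(clay, 95 - sand)            # keep sand + clay <= 100
  depth <- pmax(35 - 8 * relev + up(noise$depth), 1)
  soil_type <- matrix("rendzina", nr, nc)
  soil_type[depth > 25 & sand >= 45] <- "poor_brown"
  soil_type[depth > 25 & sand < 45] <- "rich_brown"
  soil_type[depth > 45 & clay > 25] <- "gleyic"
  pnv <- matrix("FASY;PIAB", nr, nc)
  pnv[z >= 900 & z < 1400] <- "PIAB;FASY;ABAL"
  pnv[z >= 1400 & z < 1700] <- "PIAB"
  pnv[z >= 1700] <- "PIAB;LADE;PICE"
  warm_mod <- pmax(1 + up(noise$warm_mod), 0.1)

  g <- function(v) raster_grid(v, 0, 0, cellsize_m)
  truth <- synthetic_truth(seed = seed, field_variograms = field_vgms)
  list(dem = dem, sand = g(sand), clay = g(clay), depth = g(depth),
       soil_type = soil_type, pnv = pnv, warm_mod = g(warm_mod),
       extent_m = extent_m, truth = truth)
}

#' Ground-truth record of a synthetic scene
#'
#' Records the exact coefficients the simulator uses, so downstream
#' analyses can be checked against known effects: `temp_effect` links the
#' annual temperature anomaly (degC) of a plot to its demographic rates on
#' the log scale (positive = warming amplifies change); `legacy_damping`
#' shrinks recruitment as stand basal area grows;
#' `elevation_conifer_gradient` is the logit increase in conifer
#' recruitment per km of elevation.
#'
#' @param seed integer seed.
#' @param temp_effect,legacy_damping,elevation_conifer_gradient simulator
#'   coefficients (see description).
#' @param field_variograms list recording the variogram of every generated
#'   random field.
#' @param census_years the census calendar.
#' @return List of class `synthetic_truth`.
#' @export
synthetic_truth <- function(seed = 1, temp_effect = 3,
                            legacy_damping = 1.0,
                            elevation_conifer_gradient = 2.0,
                            field_variograms = list(),
                            census_years = c(1984, 1996, 2011)) {
  stopifnot(is.finite(temp_effect), is.finite(legacy_damping),
            is.finite(elevation_conifer_gradient))
  structure(list(seed = seed, temp_effect = temp_effect,
                 legacy_damping = legacy_damping,
                 elevation_conifer_gradient = elevation_conifer_gradient,
                 field_variograms = field_variograms,
                 census_years = census_years),
            class = "synthetic_truth")
}

#' Place inventory plots on a systematic grid
#'
#' Plots sit on the nodes of a `dx` x `dy` grid (200 x 100 m by default)
#' and are kept only where the DEM is below the timberline. Each plot
#' inherits elevation, aspect, soils and PNV dominants from the underlying
#' cells. Plots in the western quarter of the landscape form the
#' management zone; the rest is strictly protected.
#'
#' @param bundle landscape bundle from [generate_terrain()].
#' @param dx,dy grid spacing in m.
#' @param timberline_m upper elevation limit for forest plots (m asl).
#' @return data.frame of plot descriptors (see [inventory_dataset()]),
#'   plus a `warm_mod` column used by [generate_climate()]. Disturbance
#'   flags are initialized to `FALSE`; see [assign_disturbance()].
#' @export
place_plots <- function(bundle, dx = 200, dy = 100, timberline_m = 1700) {
  dem <- bundle$dem
  xs <- seq(0, bundle$extent_m[1], by = dx)
  ys <- seq(0, bundle$extent_m[2], by = dy)
  nodes <- expand.grid(x_m = xs, y_m = ys, KEEP.OUT.ATTRS = FALSE)
  elev <- raster_extract(dem, nodes$x_m, nodes$y_m)
  keep <- elev < timberline_m
  nodes <- nodes[keep, , drop = FALSE]
  elev <- elev[keep]
  if (!nrow(nodes)) {
    out <- data.frame(plot_id = character(0), x_m = numeric(0),
                      y_m = numeric(0), elevation_m = numeric(0))
    return(out)
  }
  ter <- terrain_indices(dem)
  col <- pmin(pmax(floor(nodes$x_m / dem$cellsize) + 1, 1), dem$ncols)
  row_s <- pmin(pmax(floor(nodes$y_m / dem$cellsize) + 1, 1), dem$nrows)
  row <- dem$nrows - row_s + 1
  ij <- cbind(row, col)
  data.frame(
    plot_id = sprintf("p%04d", seq_len(nrow(nodes))),
    x_m = nodes$x_m, y_m = nodes$y_m,
    elevation_m = elev,
    aspect_class = ter$aspect_class[ij],
    zone = ifelse(nodes$x_m < 0.25 * bundle$extent_m[1], "managed",
                  "strict"),
    sand_pct = bundle$sand$values[ij],
    clay_pct = bundle$clay$values[ij],
    soil_depth_cm = bundle$depth$values[ij],
    soil_type = bundle$soil_type[ij],
    pnv_dominants = bundle$pnv[ij],
    disturbed_p1 = FALSE, disturbed_p2 = FALSE,
    warm_mod = bundle$warm_mod$values[ij],
    stringsAsFactors = FALSE)
}

#' Assign disturbance patches to plots
#'
#' Marks plots as disturbed in each period by dropping random rectangular
#' patches onto the landscape until roughly `fraction` of plots are
#' covered, emulating a patchy disturbance occurrence map.
#'
#' @param plots plot table from [place_plots()].
#' @param extent_m landscape extent.
#' @param fraction target disturbed fraction of plots per period.
#' @param n_periods number of inter-census periods.
#' @param seed RNG seed.
#' @return The plot table with `disturbed_p1`, `disturbed_p2`, ... set.
#' @export
assign_disturbance <- function(plots, extent_m, fraction = 0.05,
                               n_periods = 2, seed = 1) {
  set.seed(seed + 77)
  for (p in seq_len(n_periods)) {
    hit <- rep(FALSE, nrow(plots))
    guard <- 0
    while (mean(hit) < fraction && guard < 200) {
      w <- stats::runif(1, 150, 500); h <- stats::runif(1, 150, 500)
      x0 <- stats::runif(1, 0, extent_m[1] - w)
      y0 <- stats::runif(1, 0, extent_m[2] - h)
      hit <- hit | (plots$x_m >= x0 & plots$x_m <= x0 + w &
                      plots$y_m >= y0 & plots$y_m <= y0 + h)
      guard <- guard + 1
    }
    plots[[paste0("disturbed_p", p)]] <- hit
  }
  plots
}

#' Generate daily climate series per plot
#'
#' Seasonal sinusoid plus an elevation lapse, plot-level warming applied as
#' a step between the two inter-census periods, and daily white noise.
#' `warming_step` is the landscape-mean difference in annual temperature
#' between the second and first period; each plot's step is scaled by its
#' `warm_mod` (a spatially correlated sensitivity field with mean ~1), so
#' warming varies in space while averaging to the configured step.
#'
#' @param plots plot table (needs `plot_id`, `elevation_m`; `warm_mod`
#'   optional, defaults to 1).
#' @param census_years census calendar; the series spans 1 January of the
#'   first year to 31 December of the year before the last.
#' @param seed RNG seed.
#' @param warming_step landscape-mean period-2 minus period-1 annual
#'   temperature difference (degC, default 0.21).
#' @param lapse_rate temperature lapse with elevation (degC/m).
#' @param base_temp_c sea-level annual mean temperature (degC).
#' @param noise_sd standard deviation of daily temperature noise (degC).
#' @return List with `dates`, `plot_ids`, and days x plots matrices
#'   `tmean` (degC), `precip` (mm/day), `rad` (MJ m-2 day-1).
#' @export
generate_climate <- function(plots, census_years = c(1984, 1996, 2011),
                             seed = 1, warming_step = 0.21,
                             lapse_rate = -0.0065, base_temp_c = 12,
                             noise_sd = 1.5) {
  set.seed(seed + 1234)
  dates <- seq(as.Date(sprintf("%d-01-01", census_years[1])),
               as.Date(sprintf("%d-12-31", census_years[length(census_years)] - 1)),
               by = "day")
  nd <- length(dates); np <- nrow(plots)
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))
  season_t <- -9 * cos(2 * pi * (doy - 15) / 365.25)
  wm <- if ("warm_mod" %in% names(plots)) plots$warm_mod else rep(1, np)
  wm <- wm / mean(wm)   # the warming step is defined as the landscape mean
  step_on <- as.numeric(yr >= census_years[2])   # warming step at census 2
  base_i <- base_temp_c + lapse_rate * plots$elevation_m
  # seasonal warming varies around each plot's annual sensitivity, so the
  # annual anomaly is the cleanest summary of a plot's realized warming
  season_i <- match(season_of_month(as.integer(format(dates, "%m"))),
                    c("winter", "spring", "summer", "autumn"))
  eps <- matrix(stats::rnorm(4 * np, 0, 1.6), 4, np)
  eps <- sweep(eps, 2, colMeans(eps))  # seasonal jitter cancels annually
  wm_season <- matrix(wm, 4, np, byrow = TRUE) + eps
  tmean <- outer(season_t, rep(1, np)) +
    matrix(base_i, nd, np, byrow = TRUE) +
    warming_step * step_on * wm_season[season_i, , drop = FALSE] +
    matrix(stats::rnorm(nd * np, 0, noise_sd), nd, np)
  season_p <- 4 + 2.5 * sin(2 * pi * (doy - 100) / 365.25)
  precip <- pmax(outer(season_p, rep(1, np)) +
                   matrix(plots$elevation_m / 1000, nd, np, byrow = TRUE) +
                   matrix(stats::rnorm(nd * np, 0, 3), nd, np), 0)
  season_r <- 12 - 8 * cos(2 * pi * (doy - 15) / 365.25)
  rad <- pmax(outer(season_r, rep(1, np)) +
                matrix(stats::rnorm(nd * np, 0, 2), nd, np), 0)
  list(dates = dates, plot_ids = plots$plot_id,
       tmean = tmean, precip = precip, rad = rad)
}

#' Default demographic rate constants of the simulator
#'
#' The simulator is a fixture generator with simple annual rate equations,
#' not an ecological model: rates were chosen to give plausible stand
#' dynamics (about one third background mortality over three decades,
#' a few mm of annual diameter increment, gradual recruitment) at desk
#' scale.
#'
#' @return Named list: `growth_cm` baseline annual dbh increment (cm);
#'   `max_growth_cm` hard upper bound on annual increment (makes the
#'   recruit-size cap at the next census a true invariant);
#'   `mortality` baseline annual mortality probability; `recruitment`
#'   baseline expected recruits per plot and year; `disturbance_mortality`
#'   extra one-year mortality probability on disturbed plots; `recruit_cap`
#'   maximum dbh (cm) of a recruit at the census following its
#'   establishment; `crowding_ba` basal area (m2/ha) at which crowding
#'   halves growth.
#' @export
demography_defaults <- function() {
  list(growth_cm = 0.35, max_growth_cm = 1.2, mortality = 0.01,
       recruitment = 1.5, disturbance_mortality = 0.35, recruit_cap = 24,
       crowding_ba = 120)
}

#' Simulate a three-census inventory on a synthetic landscape
#'
#' Annual loop of growth, mortality and recruitment per plot, driven by the
#' plot's annual temperature anomaly (amplifying, via
#' `truth$temp_effect`) and its stand basal area (dampening recruitment via
#' `truth$legacy_damping` and increasing mortality). Conifer recruitment
#' share increases with elevation (`truth$elevation_conifer_gradient`) and
#' decreases with the temperature anomaly. Disturbed plots experience one
#' pulse of extra mortality in the middle of the disturbed period.
#' Snapshots are taken at the census years.
#'
#' @param plots plot table from [place_plots()] (after
#'   [assign_disturbance()]).
#' @param climate climate series from [generate_climate()].
#' @param truth a [synthetic_truth()].
#' @param seed RNG seed.
#' @param rates demographic constants, see [demography_defaults()].
#' @param expansion_factor stems/ha represented per record (20 for
#'   500 m2 plots).
#' @param init_trees mean initial stem count per plot.
#' @return A validated [inventory_dataset()].
#' @export
simulate_inventory <- function(plots, climate, truth, seed = 1,
                               rates = demography_defaults(),
                               expansion_factor = 20, init_trees = 22) {
  set.seed(seed + 5555)
  yrs <- truth$census_years
  species <- synthetic_species()
  np <- nrow(plots)

  # per-plot, per-year annual mean temperature and its anomaly vs the
  # full-span mean: this is the demographic forcing
  yr_of_day <- as.integer(format(climate$dates, "%Y"))
  years <- sort(unique(yr_of_day))
  t_year <- rowsum(climate$tmean, yr_of_day) /
    as.vector(table(yr_of_day))
  anom <- sweep(t_year, 2, colMeans(t_year))   # years x plots

  elev <- plots$elevation_m
  con_logit <- truth$elevation_conifer_gradient * (elev - 1100) / 1000
  sp_pool <- species$species_code
  con_sp <- sp_pool[species$conifer]
  bl_sp <- sp_pool[!species$conifer]
  pick_species <- function(n, p_conifer, elev_i) {
    conif <- stats::runif(n) < p_conifer
    # elevation-tilted weights within each guild
    w_con <- cbind(PIAB = 1.2, ABAL = pmax(1 - elev_i / 1500, 0.05),
                   LADE = 0.3 + elev_i / 2000, PICE = 0.05 + elev_i / 3000)
    w_bl <- cbind(FASY = pmax(1.5 - elev_i / 1200, 0.1), BEPE = 0.4,
                  ACPS = 0.15, SOAU = 0.3)
    out <- character(n)
    for (i in seq_len(n)) {
      if (conif[i]) out[i] <- sample(colnames(w_con), 1, prob = w_con[i, ])
      else out[i] <- sample(colnames(w_bl), 1, prob = w_bl[i, ])
    }
    out
  }

  # initial stands at the first census year
  n0 <- pmax(stats::rpois(np, init_trees), 1)
  plot_idx <- rep(seq_len(np), n0)
  dbh <- pmax(stats::rlnorm(sum(n0), log(18), 0.5), 6)
  p_con0 <- stats::plogis(0.2 + con_logit[plot_idx])
  spcode <- pick_species(sum(n0), p_con0, elev[plot_idx])
  age <- pmax(round(dbh * 4 + stats::rnorm(sum(n0), 0, 10)), 5)
  live <- data.frame(plot = plot_idx, species = spcode, dbh = dbh,
                     age = age, tree_id = seq_along(dbh),
                     stringsAsFactors = FALSE)
  next_id <- nrow(live) + 1

  snapshot <- function(live, census) {
    data.frame(plot_id = plots$plot_id[live$plot], census_id = census,
               species_code = live$species, dbh_cm = live$dbh,
               age_years = live$age, expansion_factor = expansion_factor,
               tree_id = live$tree_id, stringsAsFactors = FALSE)
  }
  records <- list(snapshot(live, yrs[1]))

  periods <- census_periods(yrs)
  dist_year <- round((periods$from + periods$to) / 2)  # mortality pulse year
  for (y in years) {
    a <- anom[match(y, years), live$plot]
    ba_plot <- rowsum(expansion_factor * pi * (live$dbh / 200)^2,
                      live$plot)
    ba_all <- numeric(np); ba_all[as.integer(rownames(ba_plot))] <- ba_plot
    ba <- ba_all[live$plot]
    # growth: positive increment, amplified by warmth, damped by crowding
    incr <- rates$growth_cm * exp(truth$temp_effect * a) *
      pmax(1 - ba / rates$crowding_ba, 0.15) *
      stats::rlnorm(nrow(live), 0, 0.25)
    live$dbh <- live$dbh + pmin(pmax(incr, 0.01), rates$max_growth_cm)
    live$age <- live$age + 1
    # mortality: baseline rising with stand basal area, plus a disturbance
    # pulse in the middle of a disturbed period
    p_die <- rates$mortality * (1 + ba / 40) *
      exp(0.6 * truth$temp_effect * a)
    # warming tilts the competitive balance against conifers: extra
    # mortality on conifer stems in warm-anomaly plots
    is_con <- live$species %in% con_sp
    p_die[is_con] <- p_die[is_con] * exp(0.5 * truth$temp_effect *
                                           a[is_con])
    for (p in seq_len(nrow(periods))) {
      if (y + 1 == dist_year[p]) {
        dist_flag <- plots[[paste0("disturbed_p", p)]][live$plot]
        p_die <- p_die + rates$disturbance_mortality * dist_flag
      }
    }
    live <- live[stats::runif(nrow(live)) >= pmin(p_die, 0.95), ,
                 drop = FALSE]
    # recruitment: amplified by warmth, damped by stand basal area
    lambda <- rates$recruitment *
      exp(truth$temp_effect * anom[match(y, years), ] -
            truth$legacy_damping * ba_all / 30)
    n_rec <- stats::rpois(np, lambda)
    if (sum(n_rec) > 0) {
      rp <- rep(seq_len(np), n_rec)
      p_con <- stats::plogis(0.2 + con_logit[rp] -
                               4 * truth$temp_effect *
                                 anom[match(y, years), rp])
      rec <- data.frame(
        plot = rp,
        species = pick_species(sum(n_rec), p_con, elev[rp]),
        dbh = stats::runif(sum(n_rec), 6, 7),
        age = sample(8:20, sum(n_rec), replace = TRUE),
        tree_id = seq(next_id, length.out = sum(n_rec)),
        stringsAsFactors = FALSE)
      next_id <- next_id + sum(n_rec)
      live <- rbind(live, rec)
    }
    if ((y + 1) %in% yrs[-1])
      records[[length(records) + 1]] <- snapshot(live, y + 1)
  }
  trees <- do.call(rbind, records)
  rownames(trees) <- NULL
  inventory_dataset(trees, plots, species, yrs)
}

#' Generate a complete synthetic scene
#'
#' Convenience orchestration: terrain, plots, disturbance, climate and the
#' three-census inventory, all from one seed. The defaults define the
#' standard desk-scale scene (a few hundred plots, roughly 10-20 thousand
#' tree records).
#'
#' @param seed integer seed controlling all randomness.
#' @param extent_m landscape extent (m).
#' @param truth a [synthetic_truth()]; its `field_variograms` slot is
#'   filled from the terrain generator.
#' @param warming_step see [generate_climate()].
#' @param timberline_m plots are placed only below this elevation.
#' @param elev_range DEM elevation range (m asl).
#' @param disturbance_fraction fraction of plots disturbed per period.
#' @param init_trees mean initial stems per plot.
#' @return List with `dataset` (an [inventory_dataset()]), `climate`,
#'   `bundle`, `plots`, and `truth`.
#' @export
synthetic_scene <- function(seed = 1, extent_m = c(4000, 2400),
                            truth = synthetic_truth(seed = seed),
                            warming_step = 0.21, timberline_m = 1700,
                            elev_range = c(603, 2713),
                            disturbance_fraction = 0.05,
                            init_trees = 22) {
  bundle <- generate_terrain(extent_m, seed = seed, elev_range = elev_range)
  truth$field_variograms <- bundle$truth$field_variograms
  truth$seed <- seed
  plots <- place_plots(bundle, timberline_m = timberline_m)
  if (!nrow(plots)) stop("no plots below the timberline; lower elev_range")
  plots <- assign_disturbance(plots, extent_m,
                              fraction = disturbance_fraction,
                              n_periods = length(truth$census_years) - 1,
                              seed = seed)
  climate <- generate_climate(plots, truth$census_years, seed = seed,
                              warming_step = warming_step)
  dataset <- simulate_inventory(plots, climate, truth, seed = seed,
                                init_trees = init_trees)
  list(dataset = dataset, climate = climate, bundle = bundle,
       plots = dataset$plots, truth = truth)
}
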