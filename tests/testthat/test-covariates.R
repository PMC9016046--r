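test_that("terrain indices reproduce their defining formulas", {
  flat <- raster_grid(matrix(500, 5, 5), cellsize = 10)
  ti <- terrain_indices(flat)
  expect_equal(ti$roughness$values, matrix(0, 5, 5))
  expect_equal(ti$tri$values, matrix(0, 5, 5))
  expect_equal(ti$tpi$values, matrix(0, 5, 5))
  expect_true(all(ti$aspect_class == "flat"))

  # center 10, eight neighbors 0 -> roughness 10, TRI 10, TPI 10
  z <- matrix(0, 3, 3); z[2, 2] <- 10
  ti <- terrain_indices(raster_grid(z, cellsize = 10))
  expect_equal(ti$roughness$values[2, 2], 10)
  expect_equal(ti$tri$values[2, 2], 10)
  expect_equal(ti$tpi$values[2, 2], 10)

  expect_error(terrain_indices(raster_grid(matrix(1, 2, 5))), "3 x 3")
})

test_that("terrain indices agree with a brute-force 3x3 loop", {
  set.seed(42)
  for (rep in 1:10) {
    nr <- sample(3:8, 1); nc <- sample(3:8, 1)
    dem <- raster_grid(matrix(runif(nr * nc, 0, 100), nr, nc),
                       cellsize = 10)
    ti <- terrain_indices(dem)
    z <- dem$values
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      nb <- c()
      for (dr in -1:1) for (dc in -1:1)
        if (!(dr == 0 && dc == 0) && r + dr >= 1 && r + dr <= nr &&
            c + dc >= 1 && c + dc <= nc)
          nb <- c(nb, z[r + dr, c + dc])
      expect_equal(ti$roughness$values[r, c],
                   max(c(nb, z[r, c])) - min(c(nb, z[r, c])))
      expect_equal(ti$tri$values[r, c], mean(abs(nb - z[r, c])))
      expect_equal(ti$tpi$values[r, c], z[r, c] - mean(nb))
    }
  }
})

test_that("aspect classes follow the steepest-descent direction", {
  south <- raster_grid(outer(seq(100, 0, length.out = 10), rep(1, 10)),
                       cellsize = 10)
  ti <- terrain_indices(south)
  expect_true(all(ti$aspect_class[2:9, 2:9] == "S"))
  east <- raster_grid(outer(rep(1, 10), seq(100, 0, length.out = 10)),
                      cellsize = 10)
  expect_true(all(terrain_indices(east)$aspect_class[2:9, 2:9] == "E"))
})

make_constant_climate <- function(n_plots = 3, value = 5,
                                  years = c(1984, 1996, 2011)) {
  dates <- seq(as.Date("1984-01-01"), as.Date("2010-12-31"), by = "day")
  m <- matrix(value, length(dates), n_plots)
  list(dates = dates, plot_ids = sprintf("p%02d", seq_len(n_plots)),
       tmean = m, precip = m, rad = m)
}

test_that("constant climate gives zero anomalies everywhere", {
  an <- climate_anomalies(make_constant_climate(), c(1984, 1996, 2011))
  clim_cols <- names(driver_categories())[driver_categories() == "climate"]
  expect_equal(nrow(an), 6)            # 3 plots x 2 periods
  expect_equal(max(abs(as.matrix(an[clim_cols]))), 0)
})

test_that("a step between periods splits into anomalies of both signs", {
  cl <- make_constant_climate(2, 5)
  yr <- as.integer(format(cl$dates, "%Y"))
  cl$tmean[yr >= 1996, ] <- 6
  an <- climate_anomalies(cl, c(1984, 1996, 2011))
  n1 <- sum(yr < 1996); n2 <- sum(yr >= 1996)
  ref <- (5 * n1 + 6 * n2) / (n1 + n2)
  a1 <- an$tmean_annual[an$period == "1984-1996"][1]
  a2 <- an$tmean_annual[an$period == "1996-2011"][1]
  expect_equal(a1, 5 - ref)
  expect_equal(a2, 6 - ref)
  # anomalies cancel over the reference span when weighted by the days of
  # each variable's own season falling inside each period
  mo <- as.integer(format(cl$dates, "%m"))
  season <- c("winter", "winter", "spring", "spring", "spring", "summer",
              "summer", "summer", "autumn", "autumn", "autumn",
              "winter")[mo]
  clim_cols <- names(driver_categories())[driver_categories() == "climate"]
  for (cc in clim_cols) {
    s <- sub(".*_", "", cc)
    in_season <- if (s == "annual") rep(TRUE, length(mo)) else season == s
    d1 <- sum(in_season & yr < 1996); d2 <- sum(in_season & yr >= 1996)
    w1 <- an[[cc]][an$period == "1984-1996"][1]
    w2 <- an[[cc]][an$period == "1996-2011"][1]
    expect_lt(abs(w1 * d1 + w2 * d2) / max(abs(w1), 1e-12), 1e-6)
  }
  # gap detection
  cl$dates <- cl$dates[-100]
  cl$tmean <- cl$tmean[-100, ]; cl$precip <- cl$precip[-100, ]
  cl$rad <- cl$rad[-100, ]
  expect_error(climate_anomalies(cl, c(1984, 1996, 2011)), "gap")
})

test_that("PNV divergence and stand age follow their definitions", {
  sp <- toy_species()
  plots <- toy_plots(1)                 # pnv_dominants = "AA"
  # 100% PNV-dominant basal area -> divergence 0
  tr <- data.frame(plot_id = "p01", census_id = 1984, species_code = "AA",
                   dbh_cm = 30, age_years = 100, expansion_factor = 20)
  ds <- toy_dataset(trees = tr, plots = plots)
  leg <- legacy_covariates(ds, 1984)
  expect_equal(leg$pnv_divergence, 0)
  expect_equal(leg$total_basal_area, 20 * pi * (30 / 200)^2)

  # share s = 0.25 -> divergence 50
  tr2 <- data.frame(plot_id = "p01", census_id = 1984,
                    species_code = c("AA", "BB"), dbh_cm = c(20, 20),
                    age_years = 50, expansion_factor = c(10, 30))
  leg2 <- legacy_covariates(toy_dataset(trees = tr2, plots = plots), 1984)
  expect_equal(leg2$pnv_divergence, 50)

  # nearest-rank 90th percentile of ages 10..100 is 90
  tr3 <- data.frame(plot_id = "p01", census_id = 1984, species_code = "AA",
                    dbh_cm = 20, age_years = seq(10, 100, 10),
                    expansion_factor = 20)
  leg3 <- legacy_covariates(toy_dataset(trees = tr3, plots = plots), 1984)
  expect_equal(leg3$stand_age, 90)

  # empty plot defaults
  plots2 <- toy_plots(2)
  leg4 <- legacy_covariates(toy_dataset(trees = tr, plots = plots2), 1984)
  expect_equal(leg4$development_stage[2], "gap_regeneration")
  expect_equal(leg4$stand_age[2], 0)
  expect_equal(leg4$pnv_divergence[2], 100)
})

test_that("pnv divergence stays in [0, 100] and basal area matches", {
  set.seed(13)
  plots <- toy_plots(1)
  for (i in 1:15) {
    tr <- random_trees(25)
    ds <- toy_dataset(trees = tr, plots = plots)
    leg <- legacy_covariates(ds, 1984)
    expect_gte(leg$pnv_divergence, 0)
    expect_lte(leg$pnv_divergence, 100)
    expect_equal(leg$total_basal_area,
                 structure_indicators(tr)[["basal_area"]])
  }
})

test_that("driver table has exactly 30 columns and complete rows", {
  set.seed(3)
  sc <- synthetic_scene(seed = 3, extent_m = c(1600, 1200),
                        init_trees = 12)
  terrain <- plot_terrain(sc$bundle$dem, sc$dataset$plots)
  an <- climate_anomalies(sc$climate, sc$dataset$census_years)
  drv <- assemble_driver_table(sc$dataset, terrain, an)
  expect_equal(ncol(drv), 32)          # keys + 30 drivers
  expect_equal(setdiff(names(drv), c("plot_id", "period")),
               names(driver_categories()))
  expect_length(driver_categories(), 30)
  expect_equal(nrow(drv), 2 * nrow(sc$dataset$plots))
  expect_false(anyNA(drv))
  # disturbance pass-through
  p1 <- drv[drv$period == "1984-1996", ]
  expect_equal(p1$disturbance_occurrence[match(sc$dataset$plots$plot_id,
                                               p1$plot_id)],
               sc$dataset$plots$disturbed_p1)
})

test_that("development stages cover the eight named classes", {
  stages <- c("gap_regeneration", "establishment", "early_optimum",
              "mid_optimum", "late_optimum", "plenter", "terminal",
              "decay")
  mk <- function(dbh, n = 10, ef = 20)
    data.frame(dbh_cm = rep(dbh, n), expansion_factor = ef)
  expect_equal(classify_development_stage(mk(8, 1, 20)), "gap_regeneration")
  expect_equal(classify_development_stage(mk(8)), "establishment")
  expect_equal(classify_development_stage(mk(15)), "early_optimum")
  expect_equal(classify_development_stage(mk(25)), "mid_optimum")
  expect_equal(classify_development_stage(mk(35)), "late_optimum")
  expect_equal(classify_development_stage(mk(50)), "terminal")
  expect_equal(classify_development_stage(mk(50, 5)), "decay")
  mixed <- data.frame(dbh_cm = c(8, 8, 8, 60, 60, 60),
                      expansion_factor = 20)
  expect_equal(classify_development_stage(mixed), "plenter")
  expect_true(all(c(classify_development_stage(mk(8)),
                    classify_development_stage(mixed)) %in% stages))
})
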