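test_that("terrain generation is deterministic and rescales exactly", {
  b1 <- generate_terrain(c(2000, 1000), seed = 4, elev_range = c(600, 2700))
  b2 <- generate_terrain(c(2000, 1000), seed = 4, elev_range = c(600, 2700))
  expect_identical(b1$dem$values, b2$dem$values)
  expect_identical(b1$sand$values, b2$sand$values)
  expect_equal(min(b1$dem$values), 600, tolerance = 1e-9)
  expect_equal(max(b1$dem$values), 2700, tolerance = 1e-9)
  expect_true(all(b1$sand$values + b1$clay$values <= 100))
  expect_error(generate_terrain(c(500, 500)), "1 x 1 km")
})

test_that("plots sit on the 200 x 100 m grid below the timberline", {
  # all terrain below the timberline: node count is fully enumerable
  b <- generate_terrain(c(2000, 1000), seed = 2, elev_range = c(600, 1500))
  pl <- place_plots(b)
  expect_equal(nrow(pl), 11 * 11)      # x: 0..2000 by 200; y: 0..1000 by 100
  expect_true(all(pl$x_m %% 200 == 0 & pl$y_m %% 100 == 0))
  # plots inherit the elevation of their DEM cell
  expect_equal(pl$elevation_m, raster_extract(b$dem, pl$x_m, pl$y_m))
  # all terrain above the timberline: no plots
  bhigh <- generate_terrain(c(2000, 1000), seed = 2,
                            elev_range = c(1800, 2700))
  expect_equal(nrow(place_plots(bhigh)), 0)
})

test_that("generated climate reproduces the configured warming step", {
  b <- generate_terrain(c(3000, 2000), seed = 6, elev_range = c(600, 1500))
  pl <- place_plots(b)
  expect_gte(nrow(pl), 100)
  cl <- generate_climate(pl, seed = 6, warming_step = 0.21)
  yr <- as.integer(format(cl$dates, "%Y"))
  step <- mean(colMeans(cl$tmean[yr >= 1996, ])) -
    mean(colMeans(cl$tmean[yr < 1996, ]))
  expect_equal(step, 0.21, tolerance = 0.02)
  # no warming
  cl0 <- generate_climate(pl, seed = 6, warming_step = 0)
  step0 <- mean(colMeans(cl0$tmean[yr >= 1996, ])) -
    mean(colMeans(cl0$tmean[yr < 1996, ]))
  expect_equal(step0, 0, tolerance = 0.02)
  # lapse rate: ~6.5 degC per 1000 m of elevation
  lm_fit <- stats::lm(colMeans(cl$tmean) ~ pl$elevation_m)
  expect_equal(unname(stats::coef(lm_fit)[2]) * 1000, -6.5,
               tolerance = 0.3)
})

test_that("the simulated inventory obeys demographic consistency", {
  sc <- synthetic_scene(seed = 9, extent_m = c(2000, 1400),
                        init_trees = 15)
  tr <- sc$dataset$trees
  yrs <- sc$dataset$census_years
  cap <- demography_defaults()$recruit_cap
  for (i in 1:2) {
    a <- tr[tr$census_id == yrs[i], ]
    b <- tr[tr$census_id == yrs[i + 1], ]
    common <- intersect(a$tree_id, b$tree_id)
    # survivors never shrink
    expect_true(all(b$dbh_cm[match(common, b$tree_id)] >=
                      a$dbh_cm[match(common, a$tree_id)]))
    # new trees are recruits in the caliper-to-cap window
    recruits <- b[!(b$tree_id %in% a$tree_id), ]
    expect_true(all(recruits$dbh_cm >= 6))
    expect_true(all(recruits$dbh_cm <= cap))
  }
  expect_true(all(tr$age_years >= 0))
  expect_true(all(tr$dbh_cm >= 6))
})

test_that("switching off mortality and recruitment conserves stems", {
  b <- generate_terrain(c(1200, 1000), seed = 10,
                        elev_range = c(600, 1500))
  pl <- assign_disturbance(place_plots(b), b$extent_m, fraction = 0,
                           seed = 10)
  cl <- generate_climate(pl, seed = 10)
  rates <- demography_defaults()
  rates$mortality <- 0; rates$recruitment <- 0
  rates$disturbance_mortality <- 0
  ds <- simulate_inventory(pl, cl, synthetic_truth(seed = 10), seed = 10,
                           rates = rates)
  it <- indicator_table(ds)
  for (p in pl$plot_id) {
    dens <- it$stand_density[it$plot_id == p][order(it$census_id[it$plot_id == p])]
    expect_equal(dens[1], dens[2])
    expect_equal(dens[2], dens[3])
    ba <- it$basal_area[it$plot_id == p][order(it$census_id[it$plot_id == p])]
    expect_true(all(diff(ba) > 0))      # growth only: strictly increasing
  }
})

test_that("the full scene is reproducible bit-for-bit from its seed", {
  s1 <- synthetic_scene(seed = 14, extent_m = c(1600, 1000),
                        init_trees = 10)
  s2 <- synthetic_scene(seed = 14, extent_m = c(1600, 1000),
                        init_trees = 10)
  expect_identical(s1$dataset$trees, s2$dataset$trees)
  expect_identical(s1$dataset$plots, s2$dataset$plots)
  expect_identical(s1$climate$tmean, s2$climate$tmean)
})

test_that("generated soil fields match their recorded variograms", {
  # the truth records the variogram each coarse-lattice noise field was
  # drawn from; regenerate one field at sampled points and compare its
  # empirical semivariogram to the recorded model at half range
  set.seed(31)
  n <- 1500
  x <- runif(n, 0, 4000); y <- runif(n, 0, 3000)
  v <- synthetic_truth()$field_variograms  # defaults: empty; use terrain's
  b <- generate_terrain(c(2000, 1000), seed = 31)
  v <- b$truth$field_variograms$sand
  set.seed(42)
  z <- simulate_gaussian_field(x, y, v$family, v$sill, v$range_m)
  emp <- empirical_semivariogram(x, y, z, cutoff = v$range_m)
  half <- which.min(abs(emp$h - v$range_m / 2))
  expected <- variogram_model_value(emp$h[half], v$family, 0, v$sill,
                                    v$range_m)
  expect_equal(emp$gamma[half], expected, tolerance = 0.2)
})
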