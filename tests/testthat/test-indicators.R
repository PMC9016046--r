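test_that("structural indicators match hand arithmetic", {
  one <- data.frame(dbh_cm = 6, expansion_factor = 20)
  s <- structure_indicators(one)
  expect_equal(s[["stand_density"]], 20)
  expect_equal(s[["basal_area"]], 20 * pi * 0.03^2)
  expect_equal(s[["large_trees"]], 0)
  expect_equal(s[["sd_dbh"]], 0)

  # strict > 50 cm boundary for large trees
  expect_equal(structure_indicators(
    data.frame(dbh_cm = 50, expansion_factor = 20))[["large_trees"]], 0)
  expect_equal(structure_indicators(
    data.frame(dbh_cm = 50.1, expansion_factor = 20))[["large_trees"]], 20)

  # weighted population SD: two equal-weight stems at 10 and 20 -> 5
  two <- data.frame(dbh_cm = c(10, 20), expansion_factor = c(20, 20))
  expect_equal(structure_indicators(two)[["sd_dbh"]], 5)

  empty <- data.frame(dbh_cm = numeric(0), expansion_factor = numeric(0))
  expect_equal(unname(structure_indicators(empty)), rep(0, 4))
})

test_that("composition indicators follow the Hill-number closed form", {
  sp <- toy_species()
  mono <- data.frame(species_code = "AA", dbh_cm = 20,
                     expansion_factor = 20)
  c1 <- composition_indicators(mono, sp)
  expect_equal(c1[["effective_species_n"]], 1)
  expect_equal(c1[["conifer_share"]], 100)
  expect_equal(c1[["late_seral_share"]], 100)
  expect_equal(c1[["early_seral_share"]], 0)

  # two species with equal basal area -> Hill number exactly 2
  pair <- data.frame(species_code = c("AA", "BB"), dbh_cm = c(20, 20),
                     expansion_factor = c(20, 20))
  expect_equal(composition_indicators(pair, sp)[["effective_species_n"]], 2)

  # proportions 0.5 / 0.3 / 0.2 -> exp of Shannon entropy
  p <- c(0.5, 0.3, 0.2)
  trio <- data.frame(species_code = c("AA", "BB", "CC"),
                     dbh_cm = 20, expansion_factor = p)
  expect_equal(composition_indicators(trio, sp)[["effective_species_n"]],
               exp(-sum(p * log(p))))

  expect_error(composition_indicators(
    data.frame(species_code = "ZZ", dbh_cm = 10, expansion_factor = 1),
    sp), "species")
})

test_that("indicator table decomposes into per-plot-census calls", {
  set.seed(21)
  tr <- rbind(random_trees(40), transform(random_trees(30),
                                          census_id = 1996),
              transform(random_trees(25), plot_id = "p02"))
  ds <- toy_dataset(trees = tr)
  it <- indicator_table(ds)
  expect_equal(nrow(it), 2 * 2)        # 2 plots x 2 censuses
  for (r in seq_len(nrow(it))) {
    sub <- ds$trees[ds$trees$plot_id == it$plot_id[r] &
                      ds$trees$census_id == it$census_id[r], ]
    expected <- c(structure_indicators(sub),
                  composition_indicators(sub, ds$species))
    expect_equal(unlist(it[r, indicator_names()]), expected)
  }
  # shares bounded, Hill number bounded by richness
  shares <- c("conifer_share", "early_seral_share", "late_seral_share",
              "rare_seral_share")
  expect_true(all(as.matrix(it[shares]) >= 0 &
                    as.matrix(it[shares]) <= 100))
})

test_that("indicators are invariant to record order and record merging", {
  set.seed(33)
  for (i in 1:20) {
    tr <- random_trees(30)
    sp <- toy_species()
    base <- c(structure_indicators(tr), composition_indicators(tr, sp))
    shuf <- tr[sample(nrow(tr)), ]
    expect_equal(c(structure_indicators(shuf),
                   composition_indicators(shuf, sp)), base)
    # merge two identical stems into one with summed expansion factor
    tr2 <- tr
    tr2$dbh_cm[2] <- tr2$dbh_cm[1]
    tr2$species_code[2] <- tr2$species_code[1]
    base2 <- c(structure_indicators(tr2), composition_indicators(tr2, sp))
    merged <- tr2[-2, ]
    merged$expansion_factor[1] <- tr2$expansion_factor[1] +
      tr2$expansion_factor[2]
    expect_equal(c(structure_indicators(merged),
                   composition_indicators(merged, sp)), base2)
  }
})

test_that("Hill number is capped by richness, equality at uniformity", {
  sp <- toy_species()
  set.seed(5)
  for (i in 1:20) {
    tr <- random_trees(15)
    hill <- composition_indicators(tr, sp)[["effective_species_n"]]
    expect_lte(hill, length(unique(tr$species_code)) + 1e-9)
  }
  uniform <- data.frame(species_code = c("AA", "BB", "CC"), dbh_cm = 20,
                        expansion_factor = 10)
  expect_equal(composition_indicators(uniform, sp)[["effective_species_n"]],
               3)
})
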