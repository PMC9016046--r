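make_two_census_table <- function(v1984, v2011, plot_ids = "p01") {
  manual_indicator_table(list(
    `1984` = c(list(plot_id = plot_ids), v1984),
    `2011` = c(list(plot_id = plot_ids), v2011)))
}

test_that("annualized change is the difference divided by the span", {
  vals0 <- setNames(as.list(rep(0, 9)), indicator_names())
  v1 <- vals0; v1$basal_area <- 20
  v2 <- vals0; v2$basal_area <- 26
  it <- make_two_census_table(v1, v2)
  ch <- annualized_change(it, 1984, 2011)
  expect_equal(ch$basal_area, 6 / 27)
  expect_equal(ch$stand_density, 0)
  expect_error(annualized_change(it, 1984, 1984), "identical")

  # 12-year example: 20 -> 26 gives +0.5 per year
  it12 <- manual_indicator_table(list(
    `1984` = c(list(plot_id = "p01"), v1),
    `1996` = c(list(plot_id = "p01"), v2)))
  expect_equal(annualized_change(it12, 1984, 1996)$basal_area, 0.5)
})

test_that("standardization scales the largest magnitude to 1, keeps signs", {
  ch <- data.frame(plot_id = c("a", "b", "c"))
  for (nm in indicator_names()) ch[[nm]] <- c(0.5, -1.0, 0.25)
  std <- standardize_changes(ch)
  expect_equal(std$basal_area, c(0.5, -1.0, 0.25))
  ch2 <- ch; ch2[indicator_names()] <- ch[indicator_names()] * 4
  expect_equal(standardize_changes(ch2)$basal_area, c(0.5, -1.0, 0.25))
  # all-zero indicator stays zero
  ch$sd_dbh <- 0
  expect_equal(standardize_changes(ch)$sd_dbh, c(0, 0, 0))
  # property: max |standardized| is 1 for non-degenerate indicators
  set.seed(17)
  for (i in 1:20) {
    ch[indicator_names()] <- matrix(rnorm(27), 3)
    std <- standardize_changes(ch)
    expect_equal(unname(apply(abs(as.matrix(std[indicator_names()])), 2,
                              max)), rep(1, 9))
  }
})

test_that("composite change averages the group's standardized changes", {
  std <- data.frame(plot_id = "p01")
  vals <- c(0.2, 0.4, 0.6, 0.8)
  for (i in seq_along(indicator_names("structure")))
    std[[indicator_names("structure")[i]]] <- vals[i]
  for (nm in indicator_names("composition")) std[[nm]] <- 0
  expect_equal(composite_change(std, "structure")$composite, 0.5)
  expect_equal(composite_change(std, "composition")$composite, 0)
  expect_error(composite_change(std, "everything"), "group")
})

test_that("acceleration differences reproduce the printed worked examples", {
  # landscape-mean period changes like the published inventory summaries:
  # basal area 0.342 then 0.344, stand density 2.136 then 4.589
  zero <- setNames(as.list(rep(0, 9)), indicator_names())
  v84 <- zero
  v96 <- zero; v96$basal_area <- 0.342 * 12; v96$stand_density <- 2.136 * 12
  v11 <- zero
  v11$basal_area <- v96$basal_area + 0.344 * 15
  v11$stand_density <- v96$stand_density + 4.589 * 15
  it <- manual_indicator_table(list(
    `1984` = c(list(plot_id = "p01"), v84),
    `1996` = c(list(plot_id = "p01"), v96),
    `2011` = c(list(plot_id = "p01"), v11)))
  acc <- acceleration_summary(it, c(1984, 1996, 2011))
  ba <- acc[acc$indicator == "basal_area", ]
  expect_equal(ba$mean_p1, 0.342)
  expect_equal(ba$mean_p2, 0.344)
  expect_equal(ba$diff_mean, 0.002)
  sd_ <- acc[acc$indicator == "stand_density", ]
  expect_equal(sd_$diff_mean, 4.589 - 2.136)
  # equal period means -> zero difference
  expect_equal(acc[acc$indicator == "sd_dbh", "diff_mean"], 0)
  expect_error(acceleration_summary(it, c(1984, 1996)), "3 censuses")
})

test_that("difference column is exactly period2 minus period1", {
  set.seed(8)
  pid <- sprintf("p%02d", 1:6)
  vals <- function() {
    v <- lapply(indicator_names(), function(x) runif(6, 0, 50))
    names(v) <- indicator_names()
    v
  }
  it <- manual_indicator_table(list(`1984` = c(list(plot_id = pid), vals()),
                                    `1996` = c(list(plot_id = pid), vals()),
                                    `2011` = c(list(plot_id = pid), vals())))
  acc <- acceleration_summary(it, c(1984, 1996, 2011))
  expect_equal(acc$diff_mean, acc$mean_p2 - acc$mean_p1)
})

test_that("full-span change is the day-weighted mean of period changes", {
  set.seed(9)
  pid <- sprintf("p%02d", 1:5)
  vals <- function() {
    v <- lapply(indicator_names(), function(x) runif(5, 0, 50))
    names(v) <- indicator_names()
    v
  }
  it <- manual_indicator_table(list(`1984` = c(list(plot_id = pid), vals()),
                                    `1996` = c(list(plot_id = pid), vals()),
                                    `2011` = c(list(plot_id = pid), vals())))
  full <- annualized_change(it, 1984, 2011)
  p1 <- annualized_change(it, 1984, 1996)
  p2 <- annualized_change(it, 1996, 2011)
  for (nm in indicator_names())
    expect_equal(full[[nm]], (12 * p1[[nm]] + 15 * p2[[nm]]) / 27)
})

test_that("elevation strata report below/above means and handle emptiness", {
  plots <- toy_plots(2)
  plots$elevation_m <- c(1000, 1600)
  ch <- data.frame(plot_id = plots$plot_id)
  for (nm in indicator_names()) ch[[nm]] <- c(1, 0)
  es <- elevation_stratified_summary(ch, plots, 1400)
  expect_equal(es$difference, rep(1, 9))
  expect_equal(es$n_below[1], 1)
  # all plots below the threshold: above-stratum undefined
  es2 <- elevation_stratified_summary(ch, plots, 2000)
  expect_true(all(is.na(es2$mean_above)))
  expect_true(all(is.na(es2$difference)))
})
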