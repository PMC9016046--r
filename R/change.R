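#' Annualized per-plot indicator change between two censuses
#'
#' `(value_b - value_a) / (year_b - year_a)` for every indicator and plot,
#' in indicator units per year.
#'
#' @param ind an indicator table from [indicator_table()].
#' @param census_a,census_b census ids (years), `census_b > census_a`.
#' @return data.frame keyed by `plot_id` with one column per indicator.
#' @export
annualized_change <- function(ind, census_a, census_b) {
  if (census_b == census_a)
    stop("identical census years: annual change undefined")
  if (census_b < census_a) stop("census_b must be later than census_a")
  cols <- indicator_names()
  a <- ind[ind$census_id == census_a, , drop = FALSE]
  b <- ind[ind$census_id == census_b, , drop = FALSE]
  if (!nrow(a) || !nrow(b))
    stop("census id(s) not present in indicator table")
  b <- b[match(a$plot_id, b$plot_id), , drop = FALSE]
  span <- census_b - census_a
  out <- data.frame(plot_id = a$plot_id)
  out[cols] <- (b[cols] - a[cols]) / span
  out
}

#' Standardize change values to a maximum magnitude of 1
#'
#' Divides each indicator's per-plot changes by the maximum absolute change
#' observed across plots, so the largest change of each indicator has
#' magnitude 1 and signs are preserved. Indicators with no nonzero change
#' are left as zeros.
#'
#' @param changes output of [annualized_change()].
#' @return data.frame of the same shape with standardized values.
#' @export
standardize_changes <- function(changes) {
  out <- changes
  for (col in indicator_names()) {
    m <- max(abs(out[[col]]))
    if (m > 0) out[[col]] <- out[[col]] / m
  }
  out
}

#' Composite change across an indicator group
#'
#' Per-plot mean of the standardized changes of all indicators in a group
#' (structure or composition), the quantity mapped as "hot spots" of change.
#'
#' @param standardized output of [standardize_changes()].
#' @param group `"structure"` or `"composition"`.
#' @return data.frame with `plot_id` and `composite`.
#' @export
composite_change <- function(standardized, group) {
  if (!group %in% c("structure", "composition"))
    stop("unknown indicator group: ", group)
  cols <- indicator_names(group)
  data.frame(plot_id = standardized$plot_id,
             composite = rowMeans(standardized[cols]))
}

#' Acceleration of change between two census periods
#'
#' For a three-census inventory: landscape means and standard deviations of
#' the per-plot annual change of each indicator in the first and second
#' period, their difference (second minus first; positive values indicate an
#' acceleration of change), and the annual change relative to the landscape
#' mean indicator level at the first census.
#'
#' @param ind an indicator table from [indicator_table()].
#' @param census_years the three census years.
#' @return data.frame with one row per indicator: `mean_p1`, `sd_p1`,
#'   `mean_p2`, `sd_p2`, `diff_mean` (= `mean_p2 - mean_p1`), `diff_sd`
#'   (SD across plots of the per-plot difference), `rel_p1`, `rel_p2`
#'   (period change divided by the 1st-census landscape mean; `NA` when the
#'   baseline mean is 0).
#' @export
acceleration_summary <- function(ind, census_years) {
  if (length(census_years) != 3)
    stop("acceleration requires exactly 3 censuses, got ",
         length(census_years))
  cols <- indicator_names()
  ch1 <- annualized_change(ind, census_years[1], census_years[2])
  ch2 <- annualized_change(ind, census_years[2], census_years[3])
  ch2 <- ch2[match(ch1$plot_id, ch2$plot_id), , drop = FALSE]
  base <- ind[ind$census_id == census_years[1], , drop = FALSE]
  sd_pop <- function(x) stats::sd(x)
  out <- data.frame(indicator = cols,
                    group = ifelse(cols %in% indicator_names("structure"),
                                   "structure", "composition"))
  out$mean_p1 <- vapply(cols, function(c) mean(ch1[[c]]), 0)
  out$sd_p1 <- vapply(cols, function(c) sd_pop(ch1[[c]]), 0)
  out$mean_p2 <- vapply(cols, function(c) mean(ch2[[c]]), 0)
  out$sd_p2 <- vapply(cols, function(c) sd_pop(ch2[[c]]), 0)
  out$diff_mean <- out$mean_p2 - out$mean_p1
  out$diff_sd <- vapply(cols, function(c) sd_pop(ch2[[c]] - ch1[[c]]), 0)
  base_mean <- vapply(cols, function(c) mean(base[[c]]), 0)
  out$rel_p1 <- ifelse(base_mean != 0, out$mean_p1 / base_mean, NA_real_)
  out$rel_p2 <- ifelse(base_mean != 0, out$mean_p2 / base_mean, NA_real_)
  rownames(out) <- NULL
  out
}

#' Elevation-stratified mean change
#'
#' Mean change per indicator below and above an elevation threshold (the
#' montane/subalpine transition by default) and the below-minus-above
#' difference. An empty stratum yields `NA` means and difference.
#'
#' @param changes per-plot change table (typically standardized).
#' @param plots plot descriptor table with `plot_id` and `elevation_m`.
#' @param threshold_m stratum boundary in m asl (default 1400).
#' @return data.frame per indicator: `mean_below`, `mean_above`,
#'   `difference` (below minus above), `n_below`, `n_above`.
#' @export
elevation_stratified_summary <- function(changes, plots, threshold_m = 1400) {
  elev <- plots$elevation_m[match(changes$plot_id, plots$plot_id)]
  below <- elev < threshold_m
  cols <- indicator_names()
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  out <- data.frame(indicator = cols)
  out$mean_below <- vapply(cols, function(c) mean_or_na(changes[[c]][below]),
                           0)
  out$mean_above <- vapply(cols, function(c) mean_or_na(changes[[c]][!below]),
                           0)
  out$difference <- out$mean_below - out$mean_above
  out$n_below <- sum(below)
  out$n_above <- sum(!below)
  rownames(out) <- NULL
  out
}
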