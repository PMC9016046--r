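#' Names and categories of the 30 candidate drivers
#'
#' Four legacy variables, two disturbance variables, fifteen climate
#' anomalies (temperature, precipitation, radiation for the four
#' meteorological seasons and the full year), and nine site variables.
#'
#' @return Named character vector: names are driver column names, values
#'   the category (`legacy`, `disturbance`, `climate`, `site`).
#' @export
driver_categories <- function() {
  clim <- as.vector(outer(c("tmean", "psum", "rad"),
                          c("winter", "spring", "summer", "autumn", "annual"),
                          paste, sep = "_"))
  c(development_stage = "legacy", total_basal_area = "legacy",
    stand_age = "legacy", pnv_divergence = "legacy",
    management_zone = "disturbance", disturbance_occurrence = "disturbance",
    stats::setNames(rep("climate", 15), clim),
    elevation = "site", aspect_class = "site", roughness = "site",
    tri = "site", tpi = "site", sand_pct = "site", clay_pct = "site",
    soil_depth_cm = "site", soil_type = "site")
}

season_of_month <- function(m) {
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")[m]
}

#' Seasonal and annual climate anomalies per plot and period
#'
#' For each climate variable (daily mean temperature, daily precipitation,
#' daily radiation) and each season (DJF/MAM/JJA/SON and annual), the
#' anomaly of a period is the mean of the daily values falling inside the
#' period (and season) minus the corresponding mean over the full reference
#' span. Period `p` covers the calendar days from 1 January of its first
#' census year to 31 December of the year before its second census year;
#' the reference span is the union of all periods, so day-count-weighted
#' anomalies sum to zero by construction.
#'
#' @param climate a climate series as produced by [generate_climate()]:
#'   list with `dates` (class `Date`, daily, gap-free), `plot_ids`, and
#'   matrices `tmean`, `precip`, `rad` of size days x plots.
#' @param census_years the census calendar (defines the periods).
#' @return data.frame keyed by (`plot_id`, `period`) with 15 anomaly
#'   columns `tmean_winter`, `psum_winter`, `rad_winter`, ...,
#'   `rad_annual`. Units are daily means (degC, mm, MJ m-2).
#' @export
climate_anomalies <- function(climate, census_years) {
  dates <- climate$dates
  gaps <- as.numeric(diff(dates))
  if (any(gaps != 1)) {
    bad <- dates[which(gaps != 1)]
    stop("daily climate series has gaps after: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  periods <- census_periods(census_years)
  yr <- as.integer(format(dates, "%Y"))
  mo <- as.integer(format(dates, "%m"))
  season <- season_of_month(mo)
  span <- yr >= periods$from[1] & yr < periods$to[nrow(periods)]
  if (!any(yr == periods$from[1]) || !any(yr == periods$to[nrow(periods)] - 1))
    stop("climate series does not cover the census reference span")
  vars <- list(tmean = climate$tmean, psum = climate$precip,
               rad = climate$rad)
  out <- list()
  for (p in seq_len(nrow(periods))) {
    in_period <- yr >= periods$from[p] & yr < periods$to[p]
    row <- data.frame(plot_id = climate$plot_ids,
                      period = periods$period[p])
    for (v in names(vars)) {
      m <- vars[[v]]
      for (s in c("winter", "spring", "summer", "autumn", "annual")) {
        sel <- if (s == "annual") rep(TRUE, length(dates)) else season == s
        ref_mean <- colMeans(m[span & sel, , drop = FALSE])
        per_mean <- colMeans(m[in_period & sel, , drop = FALSE])
        row[[paste(v, s, sep = "_")]] <- per_mean - ref_mean
      }
    }
    out[[p]] <- row
  }
  do.call(rbind, out)
}

#' Simplified stand development-stage classifier
#'
#' Assigns one of eight named development stages from quadratic mean
#' diameter (QMD), stand density and the coefficient of variation of dbh.
#' This is a coarse, threshold-based stand-in for published stage
#' classification algorithms, intended to provide a plausible categorical
#' legacy covariate; thresholds are exposed for tuning.
#'
#' @param trees tree records of one plot-census (`dbh_cm`,
#'   `expansion_factor`).
#' @param thresholds named list: `qmd_establishment`, `qmd_early`,
#'   `qmd_mid`, `qmd_late`, `cv_plenter`, `density_terminal` (n/ha).
#' @return One of `"gap_regeneration"`, `"establishment"`,
#'   `"early_optimum"`, `"mid_optimum"`, `"late_optimum"`, `"plenter"`,
#'   `"terminal"`, `"decay"`.
#' @export
classify_development_stage <- function(trees,
                                       thresholds = stage_thresholds()) {
  th <- thresholds
  if (nrow(trees) == 0) return("gap_regeneration")
  ef <- trees$expansion_factor; dbh <- trees$dbh_cm
  dens <- sum(ef)
  qmd <- sqrt(sum(ef * dbh^2) / dens)
  mu <- sum(ef * dbh) / dens
  cv <- if (mu > 0) sqrt(sum(ef * (dbh - mu)^2) / dens) / mu else 0
  if (dens < th$density_gap) return("gap_regeneration")
  if (qmd < th$qmd_establishment) return("establishment")
  if (cv > th$cv_plenter && qmd >= th$qmd_early) return("plenter")
  if (qmd < th$qmd_early) return("early_optimum")
  if (qmd < th$qmd_mid) return("mid_optimum")
  if (qmd < th$qmd_late) return("late_optimum")
  if (dens >= th$density_terminal) "terminal" else "decay"
}

#' Default thresholds for [classify_development_stage()]
#' @return Named list of thresholds (cm, n/ha, dimensionless CV).
#' @export
stage_thresholds <- function() {
  list(density_gap = 60, qmd_establishment = 12, qmd_early = 20,
       qmd_mid = 30, qmd_late = 42, cv_plenter = 0.45,
       density_terminal = 150)
}

#' Legacy covariates at one census
#'
#' Per plot: total basal area (m2/ha), stand age (90th percentile of tree
#' age, nearest-rank on the expansion-weighted age distribution), divergence
#' from the potential natural vegetation, and development stage. The PNV
#' divergence assumes PNV-dominant species should jointly hold at least 50%
#' of basal area: `max(0, (0.5 - s) / 0.5) * 100` where `s` is their
#' observed basal-area share, so meeting the expectation gives 0 and total
#' absence gives 100. Plots without trees get stage `"gap_regeneration"`,
#' age 0 and divergence 100.
#'
#' @param dataset an [inventory_dataset()].
#' @param census census id (year) at which legacies are evaluated.
#' @return data.frame with `plot_id`, `development_stage`,
#'   `total_basal_area`, `stand_age`, `pnv_divergence`.
#' @export
legacy_covariates <- function(dataset, census) {
  tr <- dataset$trees[dataset$trees$census_id == census, , drop = FALSE]
  pl <- dataset$plots
  groups <- split(seq_len(nrow(tr)), tr$plot_id)
  out <- data.frame(plot_id = pl$plot_id,
                    development_stage = "gap_regeneration",
                    total_basal_area = 0, stand_age = 0,
                    pnv_divergence = 100,
                    stringsAsFactors = FALSE)
  pnv_list <- strsplit(pl$pnv_dominants, ";", fixed = TRUE)
  for (i in seq_len(nrow(pl))) {
    idx <- groups[[as.character(pl$plot_id[i])]]
    if (is.null(idx)) next
    sub <- tr[idx, , drop = FALSE]
    ba_tree <- sub$expansion_factor * pi * (sub$dbh_cm / 200)^2
    out$total_basal_area[i] <- sum(ba_tree)
    out$stand_age[i] <- weighted_quantile_nearest(
      sub$age_years, sub$expansion_factor, 0.9)
    s <- sum(ba_tree[sub$species_code %in% pnv_list[[i]]]) / sum(ba_tree)
    out$pnv_divergence[i] <- max(0, (0.5 - s) / 0.5) * 100
    out$development_stage[i] <- classify_development_stage(sub)
  }
  out
}

#' Nearest-rank weighted quantile
#'
#' Smallest value whose cumulative weight reaches `p` of the total weight.
#' With unit weights this is the classical nearest-rank percentile.
#'
#' @param x numeric values; `NA`s are dropped together with their weights.
#' @param w positive weights.
#' @param p quantile level in (0, 1].
#' @return The quantile, or `NA` when no finite values remain.
#' @export
weighted_quantile_nearest <- function(x, w, p) {
  ok <- !is.na(x)
  x <- x[ok]; w <- w[ok]
  if (!length(x)) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= p - 1e-12)[1]]
}

#' Assemble the full driver table
#'
#' One row per (plot, period) with exactly the 30 candidate driver columns
#' of [driver_categories()]: legacies evaluated at the period's first
#' census, the disturbance flag of the period, the period's 15 climate
#' anomalies, and the static site variables.
#'
#' @param dataset an [inventory_dataset()].
#' @param terrain per-plot terrain attributes from [plot_terrain()].
#' @param anomalies output of [climate_anomalies()].
#' @return data.frame keyed by (`plot_id`, `period`) with 30 driver
#'   columns; an error is raised if any cell is missing.
#' @export
assemble_driver_table <- function(dataset, terrain, anomalies) {
  periods <- census_periods(dataset$census_years)
  pl <- dataset$plots
  clim_cols <- names(driver_categories())[driver_categories() == "climate"]
  out <- list()
  for (p in seq_len(nrow(periods))) {
    leg <- legacy_covariates(dataset, periods$from[p])
    an <- anomalies[anomalies$period == periods$period[p], , drop = FALSE]
    if (!nrow(an))
      stop("assembly error: no climate anomalies for period ",
           periods$period[p])
    m_an <- match(pl$plot_id, an$plot_id)
    m_leg <- match(pl$plot_id, leg$plot_id)
    m_ter <- match(pl$plot_id, terrain$plot_id)
    dist_col <- paste0("disturbed_p", p)
    if (!dist_col %in% names(pl))
      stop("assembly error: plot table lacks column ", dist_col)
    row <- data.frame(
      plot_id = pl$plot_id, period = periods$period[p],
      development_stage = leg$development_stage[m_leg],
      total_basal_area = leg$total_basal_area[m_leg],
      stand_age = leg$stand_age[m_leg],
      pnv_divergence = leg$pnv_divergence[m_leg],
      management_zone = pl$zone,
      disturbance_occurrence = as.logical(pl[[dist_col]]),
      stringsAsFactors = FALSE)
    row[clim_cols] <- an[m_an, clim_cols]
    row$elevation <- pl$elevation_m
    row$aspect_class <- terrain$aspect_class[m_ter]
    row$roughness <- terrain$roughness[m_ter]
    row$tri <- terrain$tri[m_ter]
    row$tpi <- terrain$tpi[m_ter]
    row$sand_pct <- pl$sand_pct
    row$clay_pct <- pl$clay_pct
    row$soil_depth_cm <- pl$soil_depth_cm
    row$soil_type <- pl$soil_type
    out[[p]] <- row
  }
  out <- do.call(rbind, out)
  drivers <- names(driver_categories())
  miss <- setdiff(drivers, names(out))
  if (length(miss))
    stop("assembly error: missing driver column(s): ",
         paste(miss, collapse = ", "))
  out <- out[c("plot_id", "period", drivers)]
  if (anyNA(out))
    stop("assembly error: missing values in driver table")
  rownames(out) <- NULL
  out
}
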