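#' Names of the nine change indicators
#'
#' Four structural indicators (basal area, stand density, large-tree
#' density, dbh variation) and five compositional ones (conifer share,
#' early/late/rare seral shares, effective species number).
#'
#' @param group `"all"`, `"structure"` or `"composition"`.
#' @return Character vector of indicator column names.
#' @export
indicator_names <- function(group = c("all", "structure", "composition")) {
  group <- match.arg(group)
  structure_ind <- c("basal_area", "stand_density", "large_trees", "sd_dbh")
  composition_ind <- c("conifer_share", "early_seral_share",
                       "late_seral_share", "rare_seral_share",
                       "effective_species_n")
  switch(group,
         all = c(structure_ind, composition_ind),
         structure = structure_ind,
         composition = composition_ind)
}

#' Structural indicators of one plot-census
#'
#' Per-hectare aggregates from the measured stems of a single plot at a
#' single census. Each stem carries an expansion factor (stems per hectare
#' it represents; 20 for a 500 m2 plot), so
#' basal area = sum(ef * pi * (dbh/200)^2) in m2/ha,
#' stand density = sum(ef), large trees = sum(ef) over stems with
#' dbh strictly greater than 50 cm, and sd_dbh is the expansion-weighted
#' population standard deviation of dbh.
#'
#' @param trees data.frame of one plot-census with columns `dbh_cm` and
#'   `expansion_factor`; may have zero rows (all indicators are then 0).
#' @param large_dbh threshold for the large-tree count (cm, strict `>`).
#' @return Named numeric vector `basal_area`, `stand_density`,
#'   `large_trees`, `sd_dbh`.
#' @export
structure_indicators <- function(trees, large_dbh = 50) {
  if (nrow(trees) == 0)
    return(c(basal_area = 0, stand_density = 0, large_trees = 0, sd_dbh = 0))
  if (any(trees$expansion_factor <= 0))
    stop("expansion factors must be positive")
  ef <- trees$expansion_factor
  dbh <- trees$dbh_cm
  ba <- sum(ef * pi * (dbh / 200)^2)
  dens <- sum(ef)
  large <- sum(ef[dbh > large_dbh])
  mu <- sum(ef * dbh) / dens
  sd_dbh <- sqrt(sum(ef * (dbh - mu)^2) / dens)
  c(basal_area = ba, stand_density = dens, large_trees = large,
    sd_dbh = sd_dbh)
}

#' Compositional indicators of one plot-census
#'
#' Basal-area shares of conifers and of the early/late/rare seral classes
#' (in percent of total basal area), and the effective species number:
#' the exponential of the Shannon entropy of basal-area proportions (Hill
#' number of order 1). Empty plots return all zeros.
#'
#' @param trees data.frame of one plot-census with columns `species_code`,
#'   `dbh_cm`, `expansion_factor`.
#' @param species species-trait table with `species_code`, `conifer`,
#'   `seral_class`.
#' @return Named numeric vector `conifer_share`, `early_seral_share`,
#'   `late_seral_share`, `rare_seral_share`, `effective_species_n`.
#' @export
composition_indicators <- function(trees, species) {
  zero <- c(conifer_share = 0, early_seral_share = 0, late_seral_share = 0,
            rare_seral_share = 0, effective_species_n = 0)
  if (nrow(trees) == 0) return(zero)
  unk <- setdiff(unique(trees$species_code), species$species_code)
  if (length(unk))
    stop("species code(s) not in species table: ",
         paste(unk, collapse = ", "))
  ba <- trees$expansion_factor * pi * (trees$dbh_cm / 200)^2
  ba_by_sp <- tapply(ba, trees$species_code, sum)
  total <- sum(ba_by_sp)
  idx <- match(names(ba_by_sp), species$species_code)
  conifer <- species$conifer[idx]
  seral <- species$seral_class[idx]
  share <- function(mask) 100 * sum(ba_by_sp[mask]) / total
  p <- as.numeric(ba_by_sp) / total
  shannon <- -sum(p * log(p))
  c(conifer_share = share(conifer),
    early_seral_share = share(seral == "early"),
    late_seral_share = share(seral == "late"),
    rare_seral_share = share(seral == "rare"),
    effective_species_n = exp(shannon))
}

#' Plot-by-census indicator table
#'
#' Applies [structure_indicators()] and [composition_indicators()] to every
#' plot at every census of the dataset. Plots with no surviving stems at a
#' census get a row of zeros, so the table always has
#' `nrow(plots) * length(census_years)` rows.
#'
#' @param dataset an [inventory_dataset()].
#' @return data.frame keyed by (`plot_id`, `census_id`) with the nine
#'   indicator columns of [indicator_names()].
#' @export
indicator_table <- function(dataset) {
  plots <- dataset$plots$plot_id
  yrs <- dataset$census_years
  grid <- expand.grid(plot_id = plots, census_id = yrs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tr <- dataset$trees
  key <- paste(tr$plot_id, tr$census_id, sep = "\r")
  groups <- split(seq_len(nrow(tr)), key)
  ind <- matrix(0, nrow(grid), 9,
                dimnames = list(NULL, indicator_names()))
  gkey <- paste(grid$plot_id, grid$census_id, sep = "\r")
  for (k in names(groups)) {
    sub <- tr[groups[[k]], , drop = FALSE]
    row <- match(k, gkey)
    ind[row, ] <- c(structure_indicators(sub),
                    composition_indicators(sub, dataset$species))
  }
  cbind(grid, as.data.frame(ind))
}
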