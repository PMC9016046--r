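#' Assemble an inventory dataset from its component tables
#'
#' Bundles tree records, plot descriptors, a species-trait table and the
#' census calendar into a validated `inventory_dataset`. Census ids are the
#' (average) calendar years of the censuses, e.g. 1984, 1996, 2011.
#'
#' @param trees data.frame with columns `plot_id`, `census_id`,
#'   `species_code`, `dbh_cm`, `age_years`, `expansion_factor`. Trees below
#'   the caliper threshold are rejected (see `min_dbh`).
#' @param plots data.frame with columns `plot_id`, `x_m`, `y_m`,
#'   `elevation_m`, `aspect_class`, `zone`, `sand_pct`, `clay_pct`,
#'   `soil_depth_cm`, `soil_type`, `pnv_dominants` (semicolon-joined species
#'   codes), `disturbed_p1`, `disturbed_p2`.
#' @param species data.frame with columns `species_code`, `conifer`
#'   (logical), `seral_class` (one of `"early"`, `"late"`, `"rare"`,
#'   `"other"`).
#' @param census_years strictly increasing integer vector of census years;
#'   every `census_id` in `trees` must be one of them.
#' @param min_dbh caliper threshold in cm; records with `dbh_cm < min_dbh`
#'   are dropped and counted (default 6, the usual threshold for
#'   permanent-plot inventories of this design).
#' @return An `inventory_dataset`: list with elements `trees`, `plots`,
#'   `species`, `census_years` and `rejected` (number of sub-threshold
#'   records removed).
#' @export
inventory_dataset <- function(trees, plots, species, census_years,
                              min_dbh = 6) {
  trees <- as.data.frame(trees)
  plots <- as.data.frame(plots)
  species <- as.data.frame(species)
  need_tree <- c("plot_id", "census_id", "species_code", "dbh_cm",
                 "age_years", "expansion_factor")
  need_plot <- c("plot_id", "x_m", "y_m", "elevation_m", "aspect_class",
                 "zone", "sand_pct", "clay_pct", "soil_depth_cm",
                 "soil_type", "pnv_dominants", "disturbed_p1",
                 "disturbed_p2")
  need_sp <- c("species_code", "conifer", "seral_class")
  for (spec in list(list(trees, need_tree, "trees"),
                    list(plots, need_plot, "plots"),
                    list(species, need_sp, "species"))) {
    miss <- setdiff(spec[[2]], names(spec[[1]]))
    if (length(miss))
      stop(sprintf("schema error in %s table: missing column(s) %s",
                   spec[[3]], paste(miss, collapse = ", ")))
  }
  census_years <- as.integer(census_years)
  keep <- trees$dbh_cm >= min_dbh
  rejected <- sum(!keep)
  trees <- trees[keep, , drop = FALSE]
  rownames(trees) <- NULL
  ds <- structure(
    list(trees = trees, plots = plots, species = species,
         census_years = census_years, min_dbh = min_dbh,
         rejected = rejected),
    class = "inventory_dataset")
  rep <- validate_inventory(ds)
  if (length(rep))
    stop("invalid inventory dataset:\n  ", paste(rep, collapse = "\n  "))
  ds
}

#' Read an inventory dataset from delimited text files
#'
#' Reads the three comma-delimited tables (trees, plots, species) and
#' validates them into an [inventory_dataset()].
#'
#' @param tree_path,plot_path,species_path CSV file paths.
#' @param census_years census calendar, see [inventory_dataset()].
#' @param min_dbh caliper threshold in cm.
#' @return An `inventory_dataset`.
#' @export
read_inventory <- function(tree_path, plot_path, species_path, census_years,
                           min_dbh = 6) {
  for (p in c(tree_path, plot_path, species_path))
    if (!file.exists(p)) stop("input table not found: ", p)
  trees <- utils::read.csv(tree_path, stringsAsFactors = FALSE)
  plots <- utils::read.csv(plot_path, stringsAsFactors = FALSE)
  species <- utils::read.csv(species_path, stringsAsFactors = FALSE)
  inventory_dataset(trees, plots, species, census_years, min_dbh = min_dbh)
}

#' Write an inventory dataset to delimited text files
#'
#' @param dataset an [inventory_dataset()].
#' @param dir output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_inventory <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(trees = file.path(dir, "trees.csv"),
             plots = file.path(dir, "plots.csv"),
             species = file.path(dir, "species.csv"))
  utils::write.csv(dataset$trees, paths["trees"], row.names = FALSE)
  utils::write.csv(dataset$plots, paths["plots"], row.names = FALSE)
  utils::write.csv(dataset$species, paths["species"], row.names = FALSE)
  invisible(paths)
}

#' Validate an inventory dataset
#'
#' Checks every structural invariant of the data model and returns a
#' character vector of human-readable violations (empty when the dataset is
#' valid). Unlike [inventory_dataset()], this never throws.
#'
#' @param dataset an `inventory_dataset` (or a bare list with the same
#'   elements).
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_inventory <- function(dataset) {
  out <- character(0)
  tr <- dataset$trees; pl <- dataset$plots; sp <- dataset$species
  yrs <- dataset$census_years
  if (length(yrs) < 2)
    out <- c(out, "at least 2 censuses are required for change analysis")
  if (is.unsorted(yrs, strictly = TRUE))
    out <- c(out, sprintf("census years not strictly increasing: %s",
                          paste(yrs, collapse = ", ")))
  if (any(tr$dbh_cm < dataset$min_dbh))
    out <- c(out, sprintf("%d tree record(s) below the %g cm dbh threshold",
                          sum(tr$dbh_cm < dataset$min_dbh), dataset$min_dbh))
  if (any(tr$expansion_factor <= 0))
    out <- c(out, "non-positive expansion factor(s) in tree table")
  orphan <- setdiff(unique(tr$plot_id), pl$plot_id)
  if (length(orphan))
    out <- c(out, sprintf("tree records reference unknown plot(s): %s",
                          paste(utils::head(orphan, 5), collapse = ", ")))
  bad_census <- setdiff(unique(tr$census_id), yrs)
  if (length(bad_census))
    out <- c(out, sprintf("tree records reference unknown census id(s): %s",
                          paste(bad_census, collapse = ", ")))
  unk_sp <- setdiff(unique(tr$species_code), sp$species_code)
  if (length(unk_sp))
    out <- c(out, sprintf("species code(s) missing from species table: %s",
                          paste(unk_sp, collapse = ", ")))
  if (anyDuplicated(sp$species_code))
    out <- c(out, "duplicate species codes in species table")
  bad_class <- setdiff(unique(sp$seral_class),
                       c("early", "late", "rare", "other"))
  if (length(bad_class))
    out <- c(out, sprintf("invalid seral class label(s): %s",
                          paste(bad_class, collapse = ", ")))
  if (any(pl$sand_pct + pl$clay_pct > 100 + 1e-9))
    out <- c(out, "sand_pct + clay_pct exceeds 100 for some plot(s)")
  if (any(pl$soil_depth_cm < 0))
    out <- c(out, "negative soil depth for some plot(s)")
  if (any(!nzchar(pl$pnv_dominants)))
    out <- c(out, "empty pnv_dominants for some plot(s)")
  if (anyDuplicated(pl$plot_id))
    out <- c(out, "duplicate plot ids in plot table")
  out
}

#' @export
print.inventory_dataset <- function(x, ...) {
  cat(sprintf(
    "inventory_dataset: %d tree records, %d plots, %d species, censuses %s\n",
    nrow(x$trees), nrow(x$plots), nrow(x$species),
    paste(x$census_years, collapse = "/")))
  if (x$rejected > 0)
    cat(sprintf("  (%d record(s) below the %g cm dbh threshold rejected)\n",
                x$rejected, x$min_dbh))
  invisible(x)
}

#' Period table of a census calendar
#'
#' The inter-census periods implied by the census years: period `p` spans
#' `[year_p, year_{p+1})`.
#'
#' @param census_years increasing census years.
#' @return data.frame with `period` (label `"1984-1996"` style), `from`,
#'   `to`, `length_years`.
#' @export
census_periods <- function(census_years) {
  k <- length(census_years) - 1
  data.frame(
    period = paste0(census_years[-length(census_years)], "-",
                    census_years[-1]),
    from = census_years[-length(census_years)],
    to = census_years[-1],
    length_years = diff(census_years))
}
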