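#' Fit driver-attribution models for every indicator and period
#'
#' For each of the nine change indicators and each inter-census period,
#' regresses the per-plot annual change on the 30 candidate drivers with
#' backward-eliminated boosted regression trees, then aggregates relative
#' influence across models weighted by cross-validated variance explained.
#' Residual spatial autocorrelation of every final model is summarized
#' with Moran's I.
#'
#' @param dataset an [inventory_dataset()].
#' @param drivers driver table from [assemble_driver_table()].
#' @param ind indicator table from [indicator_table()].
#' @param config a [brt_config()].
#' @param backward if `FALSE`, skip backward elimination and use the full
#'   30-covariate model for every response (faster; influence is then the
#'   full-model influence).
#' @param indicators subset of indicator names to model (default all nine).
#' @return List: `models` (per response-period: selection path or fit,
#'   influence over all 30 covariates, CV diagnostics, Moran's I),
#'   `aggregated` (an `aggregated_importance`), `morans`
#'   (data.frame per model).
#' @export
run_driver_attribution <- function(dataset, drivers, ind,
                                   config = brt_config(),
                                   backward = TRUE,
                                   indicators = indicator_names()) {
  periods <- census_periods(dataset$census_years)
  pl <- dataset$plots
  cov_names <- names(driver_categories())
  models <- list()
  for (p in seq_len(nrow(periods))) {
    ch <- annualized_change(ind, periods$from[p], periods$to[p])
    dr <- drivers[drivers$period == periods$period[p], , drop = FALSE]
    m <- match(ch$plot_id, dr$plot_id)
    X <- dr[m, cov_names]
    rownames(X) <- NULL
    for (resp in indicators) {
      y <- ch[[resp]]
      key <- paste(resp, periods$period[p], sep = "|")
      if (backward) {
        sel <- backward_select(X, y, config)
        fit <- sel$final_fit
        influence <- sel$influence_full
        path <- sel$path
      } else {
        fit <- fit_brt_cv(X, y, config)
        influence <- fit$influence
        path <- NULL
        sel <- NULL
      }
      xy <- pl[match(ch$plot_id, pl$plot_id), c("x_m", "y_m")]
      mi <- morans_i(fit$residuals, xy$x_m, xy$y_m)
      models[[key]] <- list(
        response = resp, period = periods$period[p],
        influence = influence,
        cv_variance_explained = fit$cv_variance_explained,
        cv_rmse = fit$cv_rmse, n_trees = fit$n_trees,
        morans_i = mi$I, morans_expectation = mi$expectation,
        path = path,
        final_covariates = if (backward) sel$final_covariates else
          cov_names)
    }
  }
  aggregated <- aggregate_importance(models)
  morans <- data.frame(
    response = vapply(models, `[[`, "", "response"),
    period = vapply(models, `[[`, "", "period"),
    morans_i = vapply(models, `[[`, 0, "morans_i"),
    expectation = vapply(models, `[[`, 0, "morans_expectation"),
    cv_variance_explained = vapply(models, `[[`, 0,
                                   "cv_variance_explained"),
    row.names = NULL)
  list(models = models, aggregated = aggregated, morans = morans)
}

#' Run the full forest-change analysis pipeline
#'
#' Orchestrates all stages on a synthetic scene (or a supplied dataset):
#' indicators, annualized and standardized change, composite change maps,
#' acceleration statistics, variogram-fitted kriging of change surfaces
#' with between-period pattern comparison, and BRT driver attribution.
#' Writes CSV/ASCII outputs and a JSON run report when `outdir` is given.
#'
#' @param seed integer seed for the synthetic scene and all stochastic
#'   stages.
#' @param scene optional pre-built scene from [synthetic_scene()]; by
#'   default one is generated from `seed`.
#' @param outdir output directory, or `NULL` to skip writing files.
#' @param kriging_cellsize interpolation resolution in m (default 100).
#' @param elevation_threshold_m montane/subalpine boundary (default 1400).
#' @param brt a [brt_config()] for the driver models.
#' @param backward passed to [run_driver_attribution()].
#' @param run_drivers,run_kriging stage switches (both on by default).
#' @return The run report: a list with the per-stage results and, when
#'   `outdir` is set, the paths of all written files.
#' @export
run_pipeline <- function(seed = 1, scene = NULL, outdir = NULL,
                         kriging_cellsize = 100,
                         elevation_threshold_m = 1400,
                         brt = brt_config(seed = seed),
                         backward = TRUE,
                         run_drivers = TRUE, run_kriging = TRUE) {
  if (is.null(scene)) scene <- synthetic_scene(seed = seed)
  dataset <- scene$dataset
  yrs <- dataset$census_years
  periods <- census_periods(yrs)
  ind <- indicator_table(dataset)

  full_change <- annualized_change(ind, yrs[1], yrs[length(yrs)])
  std <- standardize_changes(full_change)
  comp_struct <- composite_change(std, "structure")
  comp_compos <- composite_change(std, "composition")
  accel <- acceleration_summary(ind, yrs)
  strat <- elevation_stratified_summary(std, dataset$plots,
                                        elevation_threshold_m)

  pl <- dataset$plots
  xy <- pl[match(std$plot_id, pl$plot_id), c("x_m", "y_m")]

  kriging <- NULL
  if (run_kriging) {
    grid <- kriging_grid(xy$x_m, xy$y_m, kriging_cellsize)
    vgm_rows <- list(); pattern_rows <- list(); surfaces <- list()
    for (nm in indicator_names()) {
      per_surf <- list()
      for (p in seq_len(nrow(periods))) {
        chp <- annualized_change(ind, periods$from[p], periods$to[p])
        stdp <- standardize_changes(chp)
        ks <- krige_change_surface(xy$x_m, xy$y_m, stdp[[nm]], grid)
        per_surf[[p]] <- ks$surface
        if (!is.null(ks$model))
          vgm_rows[[paste(nm, p)]] <- data.frame(
            indicator = nm, period = periods$period[p],
            family = ks$model$family, nugget = ks$model$nugget,
            psill = ks$model$psill, range_m = ks$model$range_m,
            kappa = ks$model$kappa)
      }
      cmpr <- compare_patterns(per_surf[[1]], per_surf[[2]])
      pattern_rows[[nm]] <- data.frame(
        indicator = nm, rmse = cmpr$rmse,
        trend_congruence_pct = cmpr$trend_congruence_pct)
      full_surf <- krige_change_surface(xy$x_m, xy$y_m, std[[nm]], grid)
      surfaces[[nm]] <- list(full = full_surf$surface, periods = per_surf,
                             model = full_surf$model)
    }
    hot_struct <- krige_change_surface(xy$x_m, xy$y_m,
                                       comp_struct$composite, grid)
    hot_compos <- krige_change_surface(xy$x_m, xy$y_m,
                                       comp_compos$composite, grid)
    kriging <- list(
      variogram_models = do.call(rbind, vgm_rows),
      pattern_comparison = do.call(rbind, pattern_rows),
      surfaces = surfaces,
      hotspots = list(structure = hot_struct$surface,
                      composition = hot_compos$surface))
    rownames(kriging$pattern_comparison) <- NULL
  }

  drivers_res <- NULL; driver_table <- NULL
  if (run_drivers) {
    terrain <- plot_terrain(scene$bundle$dem, pl)
    anomalies <- climate_anomalies(scene$climate, yrs)
    driver_table <- assemble_driver_table(dataset, terrain, anomalies)
    drivers_res <- run_driver_attribution(dataset, driver_table, ind,
                                          config = brt,
                                          backward = backward)
  }

  report <- list(
    seed = seed, census_years = yrs,
    n_plots = nrow(pl), n_tree_records = nrow(dataset$trees),
    indicators = ind, changes = full_change, standardized = std,
    composites = list(structure = comp_struct, composition = comp_compos),
    acceleration = accel, elevation_strata = strat,
    kriging = kriging, driver_table = driver_table,
    drivers = drivers_res, truth = scene$truth)

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    wcsv <- function(df, name) {
      p <- file.path(outdir, name)
      utils::write.csv(df, p, row.names = FALSE)
      p
    }
    files <- c(
      wcsv(ind, "indicators.csv"),
      wcsv(std, "standardized_changes.csv"),
      wcsv(accel, "acceleration_summary.csv"),
      wcsv(strat, "elevation_strata.csv"),
      wcsv(cbind(comp_struct,
                 composite_composition = comp_compos$composite),
           "composites.csv"))
    if (run_kriging) {
      files <- c(files,
                 wcsv(kriging$pattern_comparison, "pattern_comparison.csv"),
                 wcsv(kriging$variogram_models, "variogram_models.csv"))
      for (grp in names(kriging$hotspots))
        files <- c(files, write_raster_ascii(
          kriging$hotspots[[grp]],
          file.path(outdir, sprintf("hotspot_%s.asc", grp))))
    }
    if (run_drivers) {
      files <- c(files,
                 wcsv(drivers_res$aggregated$covariates,
                      "drivers_importance.csv"),
                 wcsv(drivers_res$aggregated$categories,
                      "driver_categories.csv"),
                 wcsv(drivers_res$morans, "morans_i.csv"),
                 wcsv(driver_table, "drivers.csv"))
    }
    summary_json <- list(
      seed = seed, census_years = yrs, n_plots = nrow(pl),
      n_tree_records = nrow(dataset$trees),
      acceleration = accel,
      files = files)
    jp <- file.path(outdir, "run_report.json")
    jsonlite::write_json(summary_json, jp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    report$files <- c(files, jp)
  }
  report
}
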