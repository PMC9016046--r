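#' Configuration for boosted regression tree models
#'
#' @param learning_rate shrinkage per tree (default 0.01).
#' @param tree_depth maximum interaction depth of each tree (default 3).
#' @param bag_fraction row subsample fraction per tree (default 0.5).
#' @param max_trees upper limit on ensemble size; the actual number is
#'   chosen by cross-validated early stopping.
#' @param n_folds cross-validation folds (default 10).
#' @param early_stopping_rounds stop adding trees when CV error has not
#'   improved for this many rounds.
#' @param seed integer seed controlling fold assignment and bagging.
#' @return Named list of class `brt_config`.
#' @export
brt_config <- function(learning_rate = 0.01, tree_depth = 3,
                       bag_fraction = 0.5, max_trees = 5000, n_folds = 10,
                       early_stopping_rounds = 30, seed = 1) {
  stopifnot(learning_rate > 0, learning_rate <= 1, n_folds >= 2)
  structure(list(learning_rate = learning_rate, tree_depth = tree_depth,
                 bag_fraction = bag_fraction, max_trees = max_trees,
                 n_folds = n_folds,
                 early_stopping_rounds = early_stopping_rounds,
                 seed = seed),
            class = "brt_config")
}

# One-hot encode a covariate data.frame; returns the numeric matrix and a
# vector mapping each matrix column to its parent covariate.
.encode_covariates <- function(X) {
  cols <- lapply(names(X), function(nm) {
    v <- X[[nm]]
    if (is.numeric(v)) {
      m <- matrix(as.numeric(v), ncol = 1,
                  dimnames = list(NULL, nm))
      parent <- nm
    } else {
      v <- as.factor(v)
      lev <- levels(v)
      m <- vapply(lev, function(l) as.numeric(v == l),
                  numeric(length(v)))
      colnames(m) <- paste(nm, lev, sep = "..")
      parent <- rep(nm, length(lev))
    }
    list(m = m, parent = parent)
  })
  list(matrix = do.call(cbind, lapply(cols, `[[`, "m")),
       parent = unlist(lapply(cols, `[[`, "parent")))
}

.make_folds <- function(n, n_folds, seed) {
  set.seed(seed)
  idx <- sample(n)
  split(idx, rep(seq_len(n_folds), length.out = n))
}

#' Fit a cross-validated boosted regression tree model
#'
#' Gradient-boosted regression trees with squared-error loss. The ensemble
#' size is chosen by minimizing tenfold (by default) cross-validation
#' error; relative influence is the per-covariate share of the total
#' squared split improvement (gain), with dummy columns of categorical
#' covariates summed back to their parent, normalized to 100.
#'
#' @param X data.frame of covariates (numeric or categorical); no missing
#'   values.
#' @param y numeric response.
#' @param config a [brt_config()].
#' @param folds optional list of held-out index vectors; defaults to folds
#'   drawn from `config$seed`. Passing the same folds across refits makes
#'   CV errors comparable between covariate sets.
#' @return List of class `brt_fit`: `influence` (named %, sums to 100),
#'   `cv_rmse`, `cv_variance_explained` (1 - CV-SSE/SST), `n_trees`,
#'   `residuals` (observed minus out-of-fold prediction).
#' @export
fit_brt_cv <- function(X, y, config = brt_config(), folds = NULL) {
  n <- nrow(X)
  if (n < 50) stop("need at least 50 observations to fit a BRT")
  if (anyNA(X) || anyNA(y)) stop("missing values in BRT input")
  covs <- names(X)
  if (stats::sd(y) == 0) {
    warning("constant response: degenerate BRT fit, influence set to zero")
    return(structure(list(
      influence = stats::setNames(rep(0, length(covs)), covs),
      cv_rmse = 0, cv_variance_explained = 0, n_trees = 0,
      residuals = rep(0, n)), class = "brt_fit"))
  }
  enc <- .encode_covariates(X)
  dm <- xgboost::xgb.DMatrix(enc$matrix, label = y)
  if (is.null(folds)) folds <- .make_folds(n, config$n_folds, config$seed)
  params <- list(objective = "reg:squarederror",
                 eta = config$learning_rate,
                 max_depth = config$tree_depth,
                 subsample = config$bag_fraction,
                 nthread = 1, seed = config$seed)
  cv <- xgboost::xgb.cv(params = params, data = dm,
                        nrounds = config$max_trees, folds = folds,
                        early_stopping_rounds =
                          config$early_stopping_rounds,
                        prediction = TRUE, verbose = 0)
  best_iter <- cv$best_iteration
  if (is.null(best_iter) || !length(best_iter))
    best_iter <- which.min(cv$evaluation_log$test_rmse_mean)
  cv_rmse <- cv$evaluation_log$test_rmse_mean[best_iter]
  oof <- as.numeric(cv$cv_predict$pred)
  r2 <- 1 - sum((y - oof)^2) / sum((y - mean(y))^2)
  fit <- xgboost::xgb.train(params = params, data = dm,
                            nrounds = best_iter, verbose = 0)
  gain <- stats::setNames(rep(0, length(enc$parent)), colnames(enc$matrix))
  if (ncol(enc$matrix) == 1) {
    gain[] <- 1                       # single feature: all gain is its own
  } else {
    imp <- xgboost::xgb.importance(model = fit)
    if (!is.null(imp) && nrow(imp)) gain[imp$Feature] <- imp$Gain
  }
  by_parent <- tapply(gain, enc$parent, sum)[covs]
  by_parent[is.na(by_parent)] <- 0
  total <- sum(by_parent)
  influence <- if (total > 0) 100 * by_parent / total else
    stats::setNames(rep(0, length(covs)), covs)
  structure(list(influence = influence, cv_rmse = cv_rmse,
                 cv_variance_explained = r2, n_trees = best_iter,
                 residuals = y - oof),
            class = "brt_fit")
}

#' Backward covariate elimination with minimum-RMSE selection
#'
#' Starting from all covariates, repeatedly removes the single covariate
#' with the lowest relative influence (ties broken alphabetically), refits
#' with the same CV folds, and records the cross-validated RMSE of every
#' candidate set down to a single covariate. The final model is the
#' candidate with the smallest CV RMSE; RMSE ties go to the smaller set.
#' Covariates eliminated before the selected step get zero influence in
#' `influence_full`.
#'
#' @param X data.frame of covariates (>= 2 columns).
#' @param y numeric response.
#' @param config a [brt_config()].
#' @return List of class `brt_selection`: `path` (data.frame with `step`,
#'   `n_covariates`, `dropped`, `cv_rmse`), `final_covariates`,
#'   `final_fit` (a `brt_fit`), and `influence_full` (all starting
#'   covariates; eliminated ones at 0, retained ones from the final fit).
#' @export
backward_select <- function(X, y, config = brt_config()) {
  covs_all <- names(X)
  folds <- .make_folds(nrow(X), config$n_folds, config$seed)
  current <- covs_all
  fits <- list(); sets <- list(); rmses <- numeric(0)
  dropped <- character(0)
  step <- 0
  repeat {
    step <- step + 1
    fit <- fit_brt_cv(X[current], y, config, folds = folds)
    fits[[step]] <- fit; sets[[step]] <- current
    rmses[step] <- fit$cv_rmse
    if (length(current) == 1) break
    inf <- fit$influence
    ord <- order(inf, names(inf))     # least influence, ties alphabetical
    drop_cov <- names(inf)[ord[1]]
    dropped[step] <- drop_cov
    current <- setdiff(current, drop_cov)
  }
  best <- which(rmses == min(rmses))
  best <- best[length(best)]          # ties -> later step = smaller set
  final_fit <- fits[[best]]
  influence_full <- stats::setNames(rep(0, length(covs_all)), covs_all)
  influence_full[names(final_fit$influence)] <- final_fit$influence
  path <- data.frame(step = seq_along(rmses),
                     n_covariates = lengths(sets),
                     dropped = c(dropped, NA_character_)[seq_along(rmses)],
                     cv_rmse = rmses)
  structure(list(path = path, final_covariates = sets[[best]],
                 final_fit = final_fit, influence_full = influence_full,
                 best_step = best),
            class = "brt_selection")
}

#' Aggregate relative influence across response models
#'
#' Weighted mean of per-model influence vectors, with weights equal to
#' each model's cross-validated variance explained (negative values
#' clipped to 0), renormalized to sum to 100. Covariates eliminated during
#' backward selection contribute zero within their model. Aggregates are
#' reported overall and separately for structural and compositional
#' responses, each with a category rollup.
#'
#' @param models list; each element needs `response` (an indicator name),
#'   `influence` (named vector over all candidate covariates, in %) and
#'   `cv_variance_explained`.
#' @param categories named vector mapping covariates to categories
#'   (default [driver_categories()]).
#' @return List of class `aggregated_importance` with `covariates`
#'   (data.frame: covariate, category, structure_pct, composition_pct,
#'   overall_pct) and `categories` (rollup data.frame).
#' @export
aggregate_importance <- function(models, categories = driver_categories()) {
  if (!length(models)) stop("no models to aggregate")
  covs <- names(models[[1]]$influence)
  inf <- t(vapply(models, function(m) m$influence[covs],
                  numeric(length(covs))))
  w <- vapply(models, function(m) max(m$cv_variance_explained, 0), 0)
  resp <- vapply(models, function(m) m$response, "")
  agg_one <- function(rows) {
    if (!any(rows)) return(stats::setNames(rep(NA_real_, length(covs)),
                                           covs))
    wi <- w[rows]
    if (sum(wi) == 0) {
      warning("all model weights zero: using unweighted mean influence")
      wi <- rep(1, sum(rows))
    }
    v <- colSums(inf[rows, , drop = FALSE] * wi) / sum(wi)
    if (sum(v) > 0) v <- 100 * v / sum(v)
    v
  }
  overall <- agg_one(rep(TRUE, length(models)))
  struct <- agg_one(resp %in% indicator_names("structure"))
  comp <- agg_one(resp %in% indicator_names("composition"))
  cat_of <- categories[covs]
  covariate_df <- data.frame(covariate = covs, category = unname(cat_of),
                             structure_pct = unname(struct),
                             composition_pct = unname(comp),
                             overall_pct = unname(overall),
                             stringsAsFactors = FALSE)
  rollup <- function(v) tapply(v, cat_of, sum)
  cats <- sort(unique(unname(cat_of)))
  category_df <- data.frame(
    category = cats,
    structure_pct = as.numeric(rollup(struct)[cats]),
    composition_pct = as.numeric(rollup(comp)[cats]),
    overall_pct = as.numeric(rollup(overall)[cats]),
    stringsAsFactors = FALSE)
  structure(list(covariates = covariate_df, categories = category_df),
            class = "aggregated_importance")
}
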