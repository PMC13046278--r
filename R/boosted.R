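#' Train the gradient-boosted benchmark on derived window features
#'
#' Flattens every epoch window into the [derive_features()] summary vector
#' and fits an XGBoost classifier. Hyperparameters are selected from `grid`
#' by grouped 5-fold cross-validation — folds are patient-disjoint, the
#' same leakage control as the train/validation split — scoring mean CV
#' AUC, then the best configuration is refit on the full training data.
#' The default grid is the single printed-default configuration, so no
#' search runs unless one is requested.
#'
#' @param train An `epoch_dataset`.
#' @param grid Data frame of candidate hyperparameters (columns among
#'   `eta`, `max_depth`, `min_child_weight`, `subsample`,
#'   `colsample_bytree`, `nrounds`); one row per candidate. Must be
#'   non-empty.
#' @param k Number of CV folds (default 5).
#' @param seed Integer seed (fold assignment and xgboost).
#' @return A list of class `ioh_boosted`: fitted booster, chosen
#'   parameters, CV table, feature names.
#' @export
train_boosted <- function(train, grid = NULL, k = 5, seed = 1L) {
  grid <- grid %||% tibble(eta = 0.1, max_depth = 6, min_child_weight = 5,
                           subsample = 0.8, colsample_bytree = 0.8,
                           nrounds = 150)
  if (!is.data.frame(grid) || nrow(grid) == 0L) {
    abort("`grid` must be a non-empty data frame of candidate settings")
  }
  if (length(unique(train$y)) < 2L) abort("training labels are single-class")
  feats <- derive_features(train)
  y <- train$y

  # patient-disjoint folds
  pats <- unique(train$group)
  fold_of_pat <- local_seed(seed, {
    setNames(sample(rep_len(seq_len(k), length(pats))), pats)
  })
  fold <- unname(fold_of_pat[train$group])

  xparams <- function(row) {
    list(objective = "binary:logistic", eval_metric = "auc",
         eta = row$eta, max_depth = row$max_depth,
         min_child_weight = row$min_child_weight, subsample = row$subsample,
         colsample_bytree = row$colsample_bytree, nthread = 1,
         seed = as.integer(seed))
  }

  # a single candidate needs no cross-validated selection: refit directly
  if (nrow(grid) == 1L) {
    best <- dplyr::bind_cols(grid[1, ], tibble(cv_auc = NA_real_))
    bst <- xgboost::xgb.train(
      params = xparams(best),
      data = xgboost::xgb.DMatrix(feats, label = y),
      nrounds = best$nrounds, verbose = 0
    )
    return(structure(list(booster = bst, params = best, cv = best,
                          feature_names = colnames(feats), spec = train$spec,
                          horizon = train$horizon, seed = seed),
                     class = "ioh_boosted"))
  }

  cv <- purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    row <- grid[g, ]
    aucs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
        return(NA_real_)
      }
      bst <- xgboost::xgb.train(
        params = xparams(row),
        data = xgboost::xgb.DMatrix(feats[tr, , drop = FALSE], label = y[tr]),
        nrounds = row$nrounds, verbose = 0
      )
      p <- predict(bst, xgboost::xgb.DMatrix(feats[!tr, , drop = FALSE]))
      auc_point(y[!tr], p)
    }, double(1))
    dplyr::bind_cols(row, tibble(cv_auc = mean(aucs, na.rm = TRUE)))
  })
  best <- cv[which.max(cv$cv_auc), ]

  bst <- xgboost::xgb.train(
    params = xparams(best),
    data = xgboost::xgb.DMatrix(feats, label = y),
    nrounds = best$nrounds, verbose = 0
  )
  structure(list(booster = bst, params = best, cv = cv,
                 feature_names = colnames(feats), spec = train$spec,
                 horizon = train$horizon, seed = seed),
            class = "ioh_boosted")
}

#' @export
print.ioh_boosted <- function(x, ...) {
  cat(sprintf("<ioh_boosted> %d features, horizon %d min, cv AUC %.3f\n",
              length(x$feature_names), x$horizon, x$params$cv_auc))
  invisible(x)
}

#' @export
glance.ioh_boosted <- function(x, ...) {
  dplyr::bind_cols(tibble(n_features = length(x$feature_names),
                          horizon = x$horizon), x$params)
}

#' Predict probabilities from the boosted benchmark
#'
#' @param model An `ioh_boosted` model.
#' @param dataset An `epoch_dataset` (features are derived on the fly with
#'   the model's feature spec).
#' @return Numeric vector of probabilities.
#' @export
predict_proba_boosted <- function(model, dataset) {
  feats <- derive_features(dataset, model$spec)
  stopifnot(identical(colnames(feats), model$feature_names))
  predict(model$booster, xgboost::xgb.DMatrix(feats))
}
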