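#' Random-forest model configuration
#'
#' The three stated forest parameters: 80 trees, a squared-error split
#' criterion with Friedman's improvement score, and seed 0 for the
#' bootstrap randomness. Remaining hyper-parameters stay at conventional
#' defaults: trees grown to depth (node size 1), bootstrap on, and all
#' selected features considered at every split.
#'
#' @param n_trees Trees in the forest (default 80).
#' @param split_criterion Criterion label recorded for audit (default
#'   `"friedman_mse"`).
#' @param seed Seed for all model randomness (default 0).
#' @param n_selected_features Features kept by univariate selection per
#'   fold (default 5).
#' @return List of class `model_config`.
#' @export
model_config <- function(n_trees = 80, split_criterion = "friedman_mse",
                         seed = 0L, n_selected_features = 5) {
  if (n_trees < 1) stop("model_config: n_trees must be >= 1")
  if (n_selected_features < 1) {
    stop("model_config: n_selected_features must be >= 1")
  }
  structure(list(n_trees = as.integer(n_trees),
                 split_criterion = split_criterion,
                 seed = as.integer(seed),
                 n_selected_features = as.integer(n_selected_features)),
            class = "model_config")
}

#' Leave-one-session-out splits
#'
#' One split per session: that session is the test set and all others
#' train, in deterministic roster order.
#'
#' @param session_ids Character vector of session ids.
#' @return List of splits, each `list(test, train)`.
#' @export
make_loso_splits <- function(session_ids) {
  if (length(session_ids) < 2) {
    stop("make_loso_splits: need >= 2 sessions")
  }
  lapply(session_ids, function(id) {
    list(test = id, train = setdiff(session_ids, id))
  })
}

#' Univariate F-value feature selection
#'
#' For each feature, the regression F statistic on 1 and n-2 degrees of
#' freedom from its Pearson correlation r with the target:
#' F = r^2 / (1 - r^2) * (n - 2). Constant features score 0; perfectly
#' correlated ones are capped at a large finite sentinel. The `k` largest
#' win, ties broken by column order.
#'
#' @param train_features data.frame or matrix of training features.
#' @param train_targets Numeric target vector.
#' @param k Number of features to keep (default 5).
#' @return Character vector of `k` selected feature names.
#' @export
f_value_select <- function(train_features, train_targets, k = 5) {
  n <- nrow(train_features)
  if (is.null(n) || n < 3) stop("f_value_select: need >= 3 training rows")
  if (k > ncol(train_features)) {
    stop("f_value_select: k exceeds the number of features")
  }
  fv <- vapply(seq_len(ncol(train_features)), function(j) {
    x <- train_features[[j]]
    if (stats::sd(x) == 0 || stats::sd(train_targets) == 0) return(0)
    r2 <- stats::cor(x, train_targets)^2
    if (r2 >= 1 - 1e-12) return(1e15)
    r2 / (1 - r2) * (n - 2)
  }, numeric(1))
  colnames_ <- if (is.data.frame(train_features)) names(train_features)
               else colnames(train_features)
  colnames_[order(-fv)[seq_len(k)]]   # order() is stable: ties by column
}

#' Fit the random-forest effort regressor
#'
#' An ensemble of `n_trees` regression trees on bootstrap resamples, every
#' selected feature a split candidate at every node, grown to minimum node
#' size 1. All randomness derives from `config$seed`, so repeated fits on
#' the same data give identical predictions.
#'
#' @param train_features data.frame of the selected training columns.
#' @param train_targets Numeric target vector.
#' @param config A [model_config()].
#' @return Object of class `fatigue_forest` wrapping the fitted ensemble.
#' @export
fit_forest <- function(train_features, train_targets,
                       config = model_config()) {
  if (nrow(train_features) == 0) stop("fit_forest: empty training set")
  set.seed(config$seed)
  # effort targets are legitimately few-valued; silence the backend's
  # "sure you want to do regression?" nudge
  rf <- withCallingHandlers(
    randomForest::randomForest(
      x = train_features, y = train_targets,
      ntree = config$n_trees, mtry = ncol(train_features), nodesize = 1
    ),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  structure(list(model = rf, config = config), class = "fatigue_forest")
}

#' @export
predict.fatigue_forest <- function(object, newdata, ...) {
  unname(stats::predict(object$model, newdata = newdata, ...))
}

#' Gini importances of a fitted forest
#'
#' Total split-criterion decrease attributed to each feature across the
#' ensemble, normalized to sum to 1 (equal shares if the forest never
#' splits, e.g. on a constant target).
#'
#' @param forest A `fatigue_forest`.
#' @return Named numeric vector summing to 1.
#' @export
forest_importance <- function(forest) {
  imp <- forest$model$importance[, "IncNodePurity"]
  tot <- sum(imp)
  if (tot > 0) return(imp / tot)
  stats::setNames(rep(1 / length(imp), length(imp)), names(imp))
}

#' Leave-one-session-out cross-validated run
#'
#' For each split: univariate F selection on the concatenated TRAINING
#' sessions only, a random forest fit on the selected columns, prediction
#' on the held-out session, and the fitted forest's normalized
#' importances. The held-out session is never consulted during selection
#' or fitting.
#'
#' @param matrices Named list of per-session feature matrices, each a
#'   `list(features = data.frame, targets = numeric)`; identical columns
#'   across sessions.
#' @param config A [model_config()].
#' @return List of split results: `test_session`, `train_sessions`,
#'   `selected_features`, `predictions`, `targets`, `importances`.
#' @export
run_loso <- function(matrices, config = model_config()) {
  ids <- names(matrices)
  cols <- lapply(matrices, function(m) names(m$features))
  if (length(unique(cols)) != 1) {
    stop("feature columns differ across sessions")
  }
  splits <- make_loso_splits(ids)
  lapply(splits, function(sp) {
    xtr <- do.call(rbind, lapply(matrices[sp$train], `[[`, "features"))
    ytr <- unlist(lapply(matrices[sp$train], `[[`, "targets"),
                  use.names = FALSE)
    sel <- f_value_select(xtr, ytr, config$n_selected_features)
    fit <- fit_forest(xtr[sel], ytr, config)
    te <- matrices[[sp$test]]
    list(test_session = sp$test,
         train_sessions = sp$train,
         selected_features = sel,
         predictions = predict(fit, te$features[sel]),
         targets = te$targets,
         importances = forest_importance(fit))
  })
}
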