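#' Mean absolute error
#' @param predictions,targets Equal-length numeric vectors.
#' @return Scalar MAE.
#' @export
mae <- function(predictions, targets) {
  if (length(predictions) != length(targets) || length(targets) == 0) {
    stop("mae: predictions and targets must have equal nonzero length")
  }
  mean(abs(predictions - targets))
}

#' Mean squared error
#' @inheritParams mae
#' @return Scalar MSE.
#' @export
mse <- function(predictions, targets) {
  if (length(predictions) != length(targets) || length(targets) == 0) {
    stop("mse: predictions and targets must have equal nonzero length")
  }
  mean((predictions - targets)^2)
}

#' Pearson correlation between predictions and targets
#' @inheritParams mae
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_corr <- function(predictions, targets) {
  if (length(predictions) != length(targets) || length(targets) == 0) {
    stop("pearson_corr: predictions and targets must have equal nonzero length")
  }
  if (stats::sd(predictions) == 0 || stats::sd(targets) == 0) {
    stop("undefined correlation: zero variance input")
  }
  stats::cor(predictions, targets)
}

#' Scale-normalized percentage MAE
#'
#' MAE divided by the number of steps of the effort scale, so accuracies
#' reported on different self-report scales (1-5, Borg 6-20, 0-7, ...)
#' become comparable fractions.
#'
#' @param mae_value Non-negative MAE.
#' @param scale_steps Number of steps in the effort scale (>= 1).
#' @return Fraction in [0, 1].
#' @export
scale_percentage_mae <- function(mae_value, scale_steps) {
  if (mae_value < 0) stop("scale_percentage_mae: mae_value must be >= 0")
  if (scale_steps < 1) stop("scale_percentage_mae: scale_steps must be >= 1")
  mae_value / scale_steps
}

#' Aggregate Gini importances over folds
#'
#' Sums each selected feature's importance over all splits where it was
#' selected; features never selected are absent. Because per-split
#' importances each sum to 1, the aggregate totals the number of splits.
#'
#' @param split_results Output of [run_loso()].
#' @return Named numeric vector, sorted by descending summed importance.
#' @export
aggregate_importance <- function(split_results) {
  if (length(split_results) < 1) stop("aggregate_importance: no splits")
  all_imp <- unlist(lapply(split_results, `[[`, "importances"))
  sums <- tapply(all_imp, names(all_imp), sum)
  out <- as.numeric(sums)
  names(out) <- names(sums)
  sort(out, decreasing = TRUE)
}

#' Cross-validated evaluation report
#'
#' Per-split MAE, MSE and Pearson correlation, their across-split
#' arithmetic means (splits weighted equally, matching a per-dataset
#' accuracy table), and the aggregated feature importances.
#'
#' @param split_results Output of [run_loso()].
#' @param config The [model_config()] used (echoed into the report).
#' @return List of class `evaluation_report`: `per_split` (data.frame
#'   `session`, `mae`, `mse`, `corr`), `average_mae`, `average_mse`,
#'   `average_corr`, `importance_sums`, `config`.
#' @export
evaluation_report <- function(split_results, config = model_config()) {
  per <- do.call(rbind, lapply(split_results, function(r) {
    data.frame(session = r$test_session,
               mae = mae(r$predictions, r$targets),
               mse = mse(r$predictions, r$targets),
               corr = pearson_corr(r$predictions, r$targets))
  }))
  rownames(per) <- NULL
  structure(
    list(per_split = per,
         average_mae = mean(per$mae),
         average_mse = mean(per$mse),
         average_corr = mean(per$corr),
         importance_sums = aggregate_importance(split_results),
         config = config),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Leave-one-session-out evaluation (", nrow(x$per_split),
      " splits)\n", sep = "")
  print(x$per_split, digits = 4)
  cat(sprintf("average MAE %.4f | average MSE %.4f | average corr %.4f\n",
              x$average_mae, x$average_mse, x$average_corr))
  cat("top summed importances:\n")
  print(round(utils::head(x$importance_sums, 8), 4))
  invisible(x)
}

# column mask for the canned ablation presets
ablation_columns <- function(all_columns, preset) {
  site_cols <- function(sites) {
    all_columns[rowSums(sapply(sites, function(s) {
      startsWith(all_columns, paste0(s, "_"))
    })) > 0]
  }
  switch(preset,
    pelvis_sternum = site_cols(c("pelvis", "sternum")),
    pelvis_only    = site_cols("pelvis"),
    no_psd         = all_columns[!grepl("_psd_", all_columns)],
    stop("unknown ablation preset: ", preset)
  )
}

#' Sensor- or family-restricted evaluation
#'
#' Repeats the identical leave-one-session-out protocol on a column
#' subset. Canned presets: `"pelvis_sternum"` (trunk pair, 38 columns),
#' `"pelvis_only"` (19 columns), `"no_psd"` (drops all PSD peak and
#' power-weighted-sum columns, 60 columns for the full sensor set).
#'
#' @param matrices Per-session feature matrices, as for [run_loso()].
#' @param config A [model_config()].
#' @param preset One of the canned preset names, or `NULL` when `columns`
#'   is given.
#' @param columns Explicit character vector of columns to keep.
#' @return An `evaluation_report` on the restricted feature set.
#' @export
run_ablation <- function(matrices, config = model_config(),
                         preset = NULL, columns = NULL) {
  all_cols <- names(matrices[[1]]$features)
  if (is.null(columns)) {
    if (is.null(preset)) stop("run_ablation: give a preset or columns")
    columns <- ablation_columns(all_cols, preset)
  }
  if (length(columns) < config$n_selected_features) {
    stop("mask leaves ", length(columns), " columns, fewer than the ",
         config$n_selected_features, " to select")
  }
  masked <- lapply(matrices, function(m) {
    list(features = m$features[columns], targets = m$targets)
  })
  evaluation_report(run_loso(masked, config), config)
}

# fit one registry model on the already-selected columns and predict
fit_predict_model <- function(label, xtr, ytr, xte, config) {
  set.seed(config$seed)
  switch(label,
    random_forest = {
      predict(fit_forest(xtr, ytr, config), xte)
    },
    gradient_boosting = {
      bst <- xgboost::xgb.train(
        params = list(eta = 0.1, max_depth = 3, nthread = 1,
                      objective = "reg:squarederror"),
        data = xgboost::xgb.DMatrix(as.matrix(xtr), label = ytr),
        nrounds = config$n_trees)
      as.numeric(stats::predict(bst, xgboost::xgb.DMatrix(as.matrix(xte))))
    },
    decision_tree = {
      df <- cbind(.y = ytr, xtr)
      tr <- rpart::rpart(.y ~ ., data = df, method = "anova",
                         control = rpart::rpart.control(
                           cp = 0, minsplit = 2, xval = 0))
      unname(stats::predict(tr, newdata = xte))
    },
    lasso = {
      fit <- glmnet::glmnet(as.matrix(xtr), ytr, alpha = 1, lambda = 1)
      as.numeric(stats::predict(fit, as.matrix(xte), s = 1))
    },
    ridge = {
      lam <- 1 / length(ytr)
      fit <- glmnet::glmnet(as.matrix(xtr), ytr, alpha = 0, lambda = lam)
      as.numeric(stats::predict(fit, as.matrix(xte), s = lam))
    },
    svr = {
      fit <- e1071::svm(x = as.matrix(xtr), y = ytr)
      unname(stats::predict(fit, as.matrix(xte)))
    },
    stop("unknown model label: ", label)
  )
}

#' Multi-model comparison on identical splits
#'
#' Every registry model is evaluated on the same leave-one-session-out
#' splits with the same per-fold selected features (chosen once by the
#' univariate F-value, independent of model). Tree ensembles share the
#' stated tree count and seed; the other models run at conventional
#' defaults.
#'
#' @param matrices Per-session feature matrices, as for [run_loso()].
#' @param config A [model_config()].
#' @param registry Character vector of model labels, a subset of
#'   `random_forest`, `gradient_boosting`, `decision_tree`, `lasso`,
#'   `svr`, `ridge`.
#' @return data.frame `model`, `average_mae`, sorted as given.
#' @export
compare_models <- function(matrices, config = model_config(),
                           registry = c("random_forest", "gradient_boosting",
                                        "decision_tree", "lasso", "svr",
                                        "ridge")) {
  known <- c("random_forest", "gradient_boosting", "decision_tree",
             "lasso", "svr", "ridge")
  bad <- setdiff(registry, known)
  if (length(bad)) stop("unknown model label: ", paste(bad, collapse = ", "))
  ids <- names(matrices)
  splits <- make_loso_splits(ids)
  # selection once per fold, shared by all models
  fold_data <- lapply(splits, function(sp) {
    xtr <- do.call(rbind, lapply(matrices[sp$train], `[[`, "features"))
    ytr <- unlist(lapply(matrices[sp$train], `[[`, "targets"),
                  use.names = FALSE)
    sel <- f_value_select(xtr, ytr, config$n_selected_features)
    list(xtr = xtr[sel], ytr = ytr,
         xte = matrices[[sp$test]]$features[sel],
         yte = matrices[[sp$test]]$targets)
  })
  rows <- lapply(registry, function(label) {
    fold_mae <- vapply(fold_data, function(fd) {
      mae(fit_predict_model(label, fd$xtr, fd$ytr, fd$xte, config), fd$yte)
    }, numeric(1))
    data.frame(model = label, average_mae = mean(fold_mae))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permuted-target baseline
#'
#' Chance-level reference for the cross-validated MAE: the pooled window
#' targets are randomly permuted across the whole study (breaking the
#' feature-target link while preserving the target distribution), the full
#' leave-one-session-out protocol is re-run, and the average MAE recorded,
#' once per permutation.
#'
#' @param matrices Per-session feature matrices, as for [run_loso()].
#' @param config A [model_config()].
#' @param n_perm Number of permutations (default 20).
#' @param seed Seed for the permutations.
#' @return Numeric vector of `n_perm` permuted-run average MAEs.
#' @export
permutation_baseline <- function(matrices, config = model_config(),
                                 n_perm = 20, seed = 0L) {
  lens <- vapply(matrices, function(m) length(m$targets), integer(1))
  pooled <- unlist(lapply(matrices, `[[`, "targets"), use.names = FALSE)
  vapply(seq_len(n_perm), function(b) {
    set.seed(seed + b)
    perm <- sample(pooled)
    off <- 0
    shuffled <- matrices
    for (i in seq_along(shuffled)) {
      shuffled[[i]]$targets <- perm[(off + 1):(off + lens[i])]
      off <- off + lens[i]
    }
    res <- run_loso(shuffled, config)
    mean(vapply(res, function(r) mae(r$predictions, r$targets), numeric(1)))
  }, numeric(1))
}
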