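#!/usr/bin/env Rscript
# Stage 3: leave-one-session-out evaluation. Per fold: univariate F-value
# selection of 5 features on the training sessions, an 80-tree random
# forest, prediction of the held-out session's interpolated effort trend.
# Reports per-split and average MAE/MSE/correlation and the summed Gini
# importances across the 8 folds.

suppressMessages(library(fatiguetrend))

mats <- study_feature_matrices(generate_study(generator_config(seed = 1L)))
cfg <- model_config()
results <- run_loso(mats, cfg)
report <- evaluation_report(results, cfg)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.csv(report$per_split, "results/tables/loso_metrics.csv",
          row.names = FALSE)
imp <- data.frame(feature = names(report$importance_sums),
                  sum_importance = unname(report$importance_sums))
write.csv(imp, "results/tables/importance_sums.csv", row.names = FALSE)
sel <- do.call(rbind, lapply(results, function(r) {
  data.frame(session = r$test_session,
             selected = paste(r$selected_features, collapse = ";"))
}))
write.csv(sel, "results/tables/selected_features.csv", row.names = FALSE)
write_report_json(report, "results/report.json")

print(report)
cat(sprintf("MAE as a fraction of the 5-step effort scale: %.4f\n",
            scale_percentage_mae(report$average_mae, 5)))
cat("Summed importances total", round(sum(report$importance_sums), 6),
    "over", nrow(report$per_split), "folds\n")
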