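#!/usr/bin/env Rscript

# Cross-validate the seven classifier families on each subset, collect
# per-model feature importances, and aggregate them with the
# squared-importance weighting, rolled up to modalities. Writes
# results/cv_metrics.csv, results/feature_weights_<subset>.csv and
# results/modality_weights.csv.

source("analysis/00_config.R")

families <- c("DT", "RF", "LDA", "KNN", "AB", "SVM", "XGB")
eval_subsets <- c("calibration", "in_lab", "in_the_wild_41")

cv_rows <- list()
mod_rows <- list()
for (nm in eval_subsets) {
  tab <- read_feature_table(file.path(FEAT_DIR, paste0(nm, ".csv")))
  evals <- lapply(families, function(fam) {
    crossval_evaluate(tab, model_spec(fam), k = 5, iters = 5, seed = SEED)
  })
  names(evals) <- families
  for (fam in families) {
    cv_rows[[length(cv_rows) + 1]] <- data.frame(
      subset = nm, family = fam,
      accuracy = evals[[fam]]$mean_accuracy, f1 = evals[[fam]]$mean_f1)
  }
  imp <- do.call(rbind, lapply(evals, `[[`, "importance"))
  rownames(imp) <- families
  weights <- aggregate_importance(imp)
  roll <- modality_rollup(weights)
  write.csv(data.frame(feature = names(weights),
                       weight = round(unname(weights), 4)),
            file.path(RESULTS_DIR, paste0("feature_weights_", nm, ".csv")),
            row.names = FALSE)
  mod_rows[[length(mod_rows) + 1]] <- data.frame(
    subset = nm, modality = names(roll), weight = round(unname(roll), 4))
  cat(sprintf("\n%s: top features by aggregated weight:\n", nm))
  print(round(head(sort(weights, decreasing = TRUE), 7), 3))
  cat("modality ranking: ",
      paste(names(roll), round(roll, 2), collapse = ", "), "\n")
}

cv <- do.call(rbind, cv_rows)
write.csv(cv, file.path(RESULTS_DIR, "cv_metrics.csv"), row.names = FALSE)
write.csv(do.call(rbind, mod_rows),
          file.path(RESULTS_DIR, "modality_weights.csv"), row.names = FALSE)

cat("\nwithin-subset cross-validated metrics:\n")
print(reshape(cv, idvar = "subset", timevar = "family", direction = "wide"),
      digits = 2, row.names = FALSE)
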