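#!/usr/bin/env Rscript

# Window every cohort into labelled feature tables, assemble the analysis
# subsets (rebalancing the in-the-wild table to 30% and 41% minority), and
# report the class distributions. Writes feature tables under scratch/ and
# results/class_distribution.csv.

source("analysis/00_config.R")

tables <- list()
for (name in names(cohort_configs)) {
  subj_dirs <- list.dirs(file.path(REC_DIR, name), recursive = FALSE)
  cohort <- lapply(subj_dirs, read_recording)
  cohort <- lapply(cohort, preprocess_recording)
  tables[[name]] <- cohort_features(cohort, spec = window_spec(60, 30),
                                    subset = name)
  cat(sprintf("%-12s: %d windows, %.1f%% anxious, drops: %s\n",
              name, nrow(tables[[name]]$rows),
              100 * mean(tables[[name]]$rows$label),
              paste(unlist(tables[[name]]$drop_counts), collapse = "/")))
}

subsets <- assemble_subsets(tables[c("calibration", "in_lab", "in_the_wild")],
                            seed = SEED)
subsets$source <- tables$source

dist <- do.call(rbind, lapply(names(subsets), function(nm) {
  lab <- subsets[[nm]]$rows$label
  data.frame(subset = nm, n = length(lab),
             not_anxious = round(100 * mean(lab == 0), 2),
             anxious = round(100 * mean(lab == 1), 2))
}))
write.csv(dist, file.path(RESULTS_DIR, "class_distribution.csv"),
          row.names = FALSE)
cat("\nclass distribution (%):\n")
print(dist, row.names = FALSE)

for (nm in names(subsets)) {
  write_feature_table(subsets[[nm]], file.path(FEAT_DIR, paste0(nm, ".csv")))
}
cat("\nfeature tables written under ", FEAT_DIR, "\n")
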