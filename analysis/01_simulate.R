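#!/usr/bin/env Rscript

# Simulate the four cohorts (a source cohort standing in for the public
# lab dataset, plus calibration / in-lab / in-the-wild target cohorts) and
# persist them as CSV + JSON recordings under scratch/.

source("analysis/00_config.R")

for (name in names(cohort_configs)) {
  cfg <- cohort_configs[[name]]
  cat(sprintf("simulating %-12s: %d subjects x %d s ...\n",
              name, cfg$n_subjects, cfg$session_duration_s))
  cohort <- generate_cohort(cfg)
  for (rec in cohort) {
    write_recording(rec, file.path(REC_DIR, name, rec$subject_id))
  }
  anx_time <- vapply(cohort, function(r) {
    durs <- vapply(r$annotations, function(a) a$end_s - a$start_s, numeric(1))
    anx <- vapply(r$annotations, `[[`, logical(1), "anxious_truth")
    sum(durs[anx]) / sum(durs)
  }, numeric(1))
  cat(sprintf("  anxious time fraction: mean %.3f (range %.3f-%.3f)\n",
              mean(anx_time), min(anx_time), max(anx_time)))
}
cat("recordings written under ", REC_DIR, "\n")
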