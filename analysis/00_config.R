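# Shared configuration for the analysis scripts: cohort sizes, seeds and
# file locations. Sourced by every numbered driver so the whole workflow is
# reproducible end to end from one place.

library(wearanx)

SEED <- 20260922
N_SUBJECTS <- 6
SESSION_S <- 600

REC_DIR <- "scratch/recordings"
FEAT_DIR <- "scratch/features"
RESULTS_DIR <- "results"

cohort_configs <- list(
  source = cohort_config(N_SUBJECTS, "calibration",
                         session_duration_s = SESSION_S, seed = SEED + 1),
  calibration = cohort_config(N_SUBJECTS, "calibration",
                              session_duration_s = SESSION_S, seed = SEED + 2),
  in_lab = cohort_config(N_SUBJECTS, "in_lab",
                         session_duration_s = SESSION_S, seed = SEED + 3),
  in_the_wild = cohort_config(N_SUBJECTS, "in_the_wild",
                              wild_anxious_frac = 0.1934,
                              session_duration_s = SESSION_S,
                              seed = SEED + 4))

for (d in c(REC_DIR, FEAT_DIR, RESULTS_DIR)) {
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
}
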