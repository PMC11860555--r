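#' Subject physiology profile
#'
#' Bundles the ground-truth physiological parameters of one simulated wearer:
#' resting heart rate and RR-interval variability (SDNN), respiration rate and
#' inhale/exhale asymmetry, tonic electrodermal level and skin-conductance
#' response (SCR) rate, skin temperature, and the additive shifts applied when
#' the subject is in the anxious state.
#'
#' @param baseline_hr resting heart rate, beats/min (40-180).
#' @param sdnn standard deviation of RR intervals, seconds (>= 0).
#' @param resp_rate respiration rate, breaths/min (6-40).
#' @param ie_ratio inhale/exhale duration ratio (> 0).
#' @param eda_tonic tonic skin conductance, microsiemens (>= 0).
#' @param scr_rate skin-conductance responses per minute (>= 0).
#' @param temp_base baseline distal skin temperature, degrees C.
#' @param anxiety_deltas named list of additive shifts applied in the anxious
#'   state: `hr_delta` (bpm, > 0), `sdnn_delta` (s, typically < 0),
#'   `resp_delta` (breaths/min), `scr_delta` (SCR/min), `temp_delta` (deg C).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(baseline_hr = 70, sdnn = 0.05, resp_rate = 14,
                            ie_ratio = 0.8, eda_tonic = 2, scr_rate = 3,
                            temp_base = 33,
                            anxiety_deltas = list(hr_delta = 15,
                                                  sdnn_delta = -0.02,
                                                  resp_delta = 4,
                                                  scr_delta = 6,
                                                  temp_delta = -0.5)) {
  if (!is.numeric(baseline_hr) || baseline_hr < 40 || baseline_hr > 180) {
    stop("`baseline_hr` must lie in [40, 180] beats/min", call. = FALSE)
  }
  if (!is.numeric(sdnn) || sdnn < 0) stop("`sdnn` must be >= 0", call. = FALSE)
  if (!is.numeric(resp_rate) || resp_rate < 6 || resp_rate > 40) {
    stop("`resp_rate` must lie in [6, 40] breaths/min", call. = FALSE)
  }
  stopifnot_positive(ie_ratio, "ie_ratio")
  if (eda_tonic < 0 || scr_rate < 0) {
    stop("`eda_tonic` and `scr_rate` must be >= 0", call. = FALSE)
  }
  deltas <- list(hr_delta = 0, sdnn_delta = 0, resp_delta = 0,
                 scr_delta = 0, temp_delta = 0)
  deltas[names(anxiety_deltas)] <- anxiety_deltas
  if (!all(vapply(deltas, is.finite, logical(1)))) {
    stop("anxiety deltas must be finite", call. = FALSE)
  }
  structure(list(baseline_hr = baseline_hr, sdnn = sdnn,
                 resp_rate = resp_rate, ie_ratio = ie_ratio,
                 eda_tonic = eda_tonic, scr_rate = scr_rate,
                 temp_base = temp_base, anxiety_deltas = deltas),
            class = "subject_profile")
}

#' Condition interval annotation
#'
#' One contiguous block of a recording session: a protocol condition (guided
#' relaxation, cold pressor, TSST, seated/walking Stroop, or unconstrained
#' "wild" time), its span in seconds, the short-form state-anxiety (STAI Y6)
#' score attached to it, and the generator-side anxious/non-anxious truth.
#'
#' @param start_s,end_s interval bounds, seconds (`end_s > start_s`).
#' @param condition one of `"relaxation"`, `"cold_pressor"`, `"tsst"`,
#'   `"stroop_seated"`, `"stroop_walking"`, `"wild"`.
#' @param stai_y6 integer STAI Y6 score in 6..24, or `NA` (filled in by
#'   [generate_session()]).
#' @param anxious_truth logical generator-side state; defaults to the
#'   condition's canonical state (relaxation is calm, induction tasks are
#'   anxious; `"wild"` requires an explicit value).
#' @return An object of class `condition_interval`.
#' @export
condition_interval <- function(start_s, end_s, condition,
                               stai_y6 = NA_integer_, anxious_truth = NULL) {
  conditions <- c("relaxation", "cold_pressor", "tsst",
                  "stroop_seated", "stroop_walking", "wild")
  if (!is.character(condition) || !condition %in% conditions) {
    stop("unknown condition label: ", condition, call. = FALSE)
  }
  if (!is.numeric(start_s) || !is.numeric(end_s) || end_s <= start_s) {
    stop("`end_s` must be greater than `start_s`", call. = FALSE)
  }
  if (!is.na(stai_y6) && (stai_y6 < 6 || stai_y6 > 24)) {
    stop("`stai_y6` must lie in [6, 24]", call. = FALSE)
  }
  if (is.null(anxious_truth)) {
    if (condition == "wild") {
      stop("`anxious_truth` must be given explicitly for 'wild' intervals",
           call. = FALSE)
    }
    anxious_truth <- condition %in% c("cold_pressor", "tsst",
                                      "stroop_seated", "stroop_walking")
  }
  structure(list(start_s = start_s, end_s = end_s, condition = condition,
                 stai_y6 = as.integer(stai_y6),
                 anxious_truth = isTRUE(anxious_truth)),
            class = "condition_interval")
}

## activity implied by a protocol condition
condition_activity <- function(condition) {
  switch(condition,
         relaxation = "seated", cold_pressor = "seated",
         tsst = "standing", stroop_seated = "seated",
         stroop_walking = "walking", wild = "variable",
         stop("unknown condition label: ", condition, call. = FALSE))
}

validate_plan <- function(plan) {
  if (length(plan) == 0L) stop("empty session plan", call. = FALSE)
  ok <- vapply(plan, inherits, logical(1), "condition_interval")
  if (!all(ok)) stop("plan entries must be condition_interval objects",
                     call. = FALSE)
  starts <- vapply(plan, `[[`, numeric(1), "start_s")
  ends <- vapply(plan, `[[`, numeric(1), "end_s")
  if (is.unsorted(starts, strictly = TRUE)) {
    stop("plan intervals must be ordered by start time", call. = FALSE)
  }
  if (any(starts[-1] < ends[-length(ends)] - 1e-9)) {
    stop("plan intervals must not overlap", call. = FALSE)
  }
  invisible(plan)
}

#' Cohort configuration
#'
#' @param n_subjects number of simulated wearers (>= 1).
#' @param subset one of `"calibration"` (seated protocol blocks in a fixed
#'   environment), `"in_lab"` (seated/standing/walking protocol blocks, fixed
#'   environment), `"in_the_wild"` (variable activity and environmental noise,
#'   imbalanced classes).
#' @param wild_anxious_frac target anxious time fraction for the
#'   in-the-wild subset; default 0.1934.
#' @param session_duration_s session length per subject, seconds.
#' @param seed integer master seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, subset, wild_anxious_frac = 0.1934,
                          session_duration_s = 600, seed = 1) {
  subsets <- c("calibration", "in_lab", "in_the_wild")
  if (!subset %in% subsets) stop("unknown subset: ", subset, call. = FALSE)
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  if (wild_anxious_frac <= 0 || wild_anxious_frac >= 1) {
    stop("`wild_anxious_frac` must lie in (0, 1)", call. = FALSE)
  }
  stopifnot_positive(session_duration_s, "session_duration_s")
  structure(list(n_subjects = as.integer(n_subjects), subset = subset,
                 wild_anxious_frac = wild_anxious_frac,
                 session_duration_s = session_duration_s,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default per-channel sampling rates
#'
#' Chest-worn channels follow the smart-shirt convention (ECG 256 Hz, RESP
#' 128 Hz, chest accelerometer 64 Hz). Wrist-device rates follow public
#' device documentation: BVP 64 Hz, EDA 4 Hz, TEMP 4 Hz, wrist accelerometer
#' 32 Hz. All rates are per-channel fields of the recording and overridable.
#'
#' @return Named numeric vector of sampling rates in Hz.
#' @export
channel_rates <- function() {
  c(ECG = 256, RESP = 128, ACC_C_x = 64, ACC_C_y = 64, ACC_C_z = 64,
    BVP = 64, EDA = 4, TEMP = 4, ACC_w_x = 32, ACC_w_y = 32, ACC_w_z = 32)
}

channel_devices <- function() {
  c(ECG = "chest", RESP = "chest", ACC_C_x = "chest", ACC_C_y = "chest",
    ACC_C_z = "chest", BVP = "wrist", EDA = "wrist", TEMP = "wrist",
    ACC_w_x = "wrist", ACC_w_y = "wrist", ACC_w_z = "wrist")
}
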