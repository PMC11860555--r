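## Sliding-window feature extraction. Each window yields the canonical
## 21-feature set spanning ECG (instantaneous-HR statistics), respiration
## (rate, amplitude, inhale/exhale timing), EDA, BVP, skin temperature and
## both accelerometers. Windows failing a per-modality precondition are
## dropped and counted, never emitted with NAs.

#' Sliding-window specification
#'
#' @param length_s window length, seconds (default 60).
#' @param shift_s window shift, seconds (default 30; must be in
#'   `(0, length_s]`).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_s = 60, shift_s = 30) {
  stopifnot_positive(length_s, "length_s")
  if (shift_s <= 0 || shift_s > length_s) {
    stop("`shift_s` must lie in (0, length_s]", call. = FALSE)
  }
  structure(list(length_s = length_s, shift_s = shift_s),
            class = "window_spec")
}

#' Canonical feature names and their modalities
#'
#' `ACC_net_w_*` features are wrist-device net acceleration, `ACC_x_*` wrist
#' x-axis, and `ACC_x_C_std` the chest x-axis spread (w = wrist device,
#' C = chest strap).
#'
#' @return Named character vector mapping feature name to modality.
#' @export
feature_modality_map <- function() {
  c(ECG_bpm = "ECG", ECG_min = "ECG", ECG_max = "ECG", ECG_std = "ECG",
    Resp_rate = "RESP", Resp_mean = "RESP", Resp_min = "RESP",
    Resp_IE = "RESP", Resp_Inhal_mean = "RESP", Resp_Exhal_std = "RESP",
    EDA_mean = "EDA", EDA_max = "EDA", EDA_drange = "EDA",
    BVP_peak_freq = "BVP", BVP_max = "BVP",
    TEMP_mean = "TEMP",
    ACC_net_w_mean = "ACC", ACC_net_w_std = "ACC", ACC_x_mean = "ACC",
    ACC_x_min = "ACC", ACC_x_C_std = "ACC")
}

#' ECG window features from detected beats
#'
#' Statistics of the instantaneous heart-rate series (60/RR) formed from the
#' beats falling inside the window: mean, min, max and population standard
#' deviation, all in beats/min.
#'
#' @param peaks a [peak_result()] for the whole record.
#' @param start_s,end_s window bounds, seconds.
#' @return Named list of `ECG_bpm`, `ECG_min`, `ECG_max`, `ECG_std`, or
#'   `NULL` (row-drop) when fewer than 3 beats fall in the window.
#' @export
ecg_features <- function(peaks, start_s, end_s) {
  tb <- peaks$times_s[peaks$times_s >= start_s & peaks$times_s < end_s]
  if (length(tb) < 3) return(NULL)
  hr <- rr_to_hr(diff(tb))
  list(ECG_bpm = mean(hr), ECG_min = min(hr), ECG_max = max(hr),
       ECG_std = pop_sd(hr))
}

## rising zero-crossing times (linear interpolation between samples)
rising_crossings <- function(x, fs) {
  n <- length(x)
  i <- which(x[-n] <= 0 & x[-1] > 0)
  if (length(i) == 0) return(numeric(0))
  frac <- -x[i] / (x[i + 1] - x[i])
  frac[!is.finite(frac)] <- 0
  (i - 1 + frac) / fs
}

#' Respiration window features
#'
#' The mean-removed, low-pass-smoothed signal is segmented at rising
#' zero-crossings into breath cycles. Within each cycle the peak marks the
#' end of the inhale; the trough between consecutive peaks marks the turn
#' from exhale to the next inhale, so inhale duration is trough-to-peak and
#' exhale duration peak-to-trough (for a smooth respiration trace the
#' mid-limb zero-crossings delimit cycles but sit inside the limbs, so
#' timing is taken from the extrema). Emits breaths/min, raw-amplitude mean
#' and min, the inhale/exhale duration ratio, mean inhale duration and the
#' population standard deviation of exhale durations.
#'
#' @param series respiration samples in the window.
#' @param fs sampling rate, Hz.
#' @param smooth_cutoff smoothing low-pass cutoff, Hz (default 2.5: low
#'   enough to suppress sensor noise between extrema, high enough to keep
#'   the waveform harmonics that carry inhale/exhale asymmetry).
#' @return Named feature list, or `NULL` (row-drop) with fewer than 2
#'   complete cycles.
#' @export
resp_features <- function(series, fs, smooth_cutoff = 2.5) {
  if (length(series) < 4 || !any(is.finite(series))) return(NULL)
  x <- series - mean(series)
  if (fs > 2 * smooth_cutoff * 1.1) {
    x <- lowpass_butterworth(x, fs, smooth_cutoff, order = 2)
  }
  cross <- rising_crossings(x, fs)
  if (length(cross) < 3) return(NULL)  # < 2 complete cycles
  n_cyc <- length(cross) - 1
  ## one peak per crossing-delimited cycle, then troughs between peaks
  peaks_t <- vapply(seq_len(n_cyc), function(c_i) {
    i0 <- max(1L, floor(cross[c_i] * fs) + 1L)
    i1 <- min(length(x), ceiling(cross[c_i + 1] * fs))
    (i0 - 1 + which.max(x[i0:i1]) - 1) / fs
  }, numeric(1))
  inhale <- numeric(0)
  exhale <- numeric(0)
  if (length(peaks_t) >= 2) {
    for (p_i in seq_len(length(peaks_t) - 1)) {
      i0 <- floor(peaks_t[p_i] * fs) + 1L
      i1 <- min(length(x), ceiling(peaks_t[p_i + 1] * fs))
      trough_t <- (i0 - 1 + which.min(x[i0:i1]) - 1) / fs
      exhale <- c(exhale, trough_t - peaks_t[p_i])
      inhale <- c(inhale, peaks_t[p_i + 1] - trough_t)
    }
  }
  ok <- inhale > 0 & exhale > 0
  if (sum(ok) < 1) return(NULL)
  list(Resp_rate = n_cyc / (cross[length(cross)] - cross[1]) * 60,
       Resp_mean = mean(series),
       Resp_min = min(series),
       Resp_IE = mean(inhale[ok]) / mean(exhale[ok]),
       Resp_Inhal_mean = mean(inhale[ok]),
       Resp_Exhal_std = pop_sd(exhale[ok]))
}

#' EDA window features
#'
#' @param series EDA samples in the window, microsiemens.
#' @return `EDA_mean`, `EDA_max`, `EDA_drange` (max - min), or `NULL` for an
#'   empty window.
#' @export
eda_features <- function(series) {
  if (length(series) == 0 || !any(is.finite(series))) return(NULL)
  list(EDA_mean = mean(series), EDA_max = max(series),
       EDA_drange = max(series) - min(series))
}

#' BVP window features
#'
#' `BVP_peak_freq` is the periodogram argmax over the cardiac band
#' (0.5-3.5 Hz) of the mean-removed signal; `BVP_max` the maximum sample.
#' Windows shorter than 10 s (insufficient spectral resolution) or with no
#' in-band power are dropped.
#'
#' @param series BVP samples in the window.
#' @param fs sampling rate, Hz.
#' @return Named feature list or `NULL` (row-drop).
#' @export
bvp_features <- function(series, fs) {
  n <- length(series)
  if (n < 10 * fs) return(NULL)
  x <- series - mean(series)
  p <- Mod(fft(x))^2
  freq <- (seq_len(n) - 1) * fs / n
  band <- which(freq >= 0.5 & freq <= 3.5)
  if (length(band) == 0 || max(p[band]) <= n * 1e-24) return(NULL)
  list(BVP_peak_freq = freq[band[which.max(p[band])]],
       BVP_max = max(series))
}

#' Accelerometer window features
#'
#' Net (vector-magnitude) acceleration statistics on the wrist device, wrist
#' x-axis location statistics, and the chest x-axis spread.
#'
#' @param chest_xyz,wrist_xyz lists with numeric `x`, `y`, `z` series for
#'   the window.
#' @return Named feature list, or `NULL` when either device is absent.
#' @export
acc_features <- function(chest_xyz, wrist_xyz) {
  if (is.null(chest_xyz) || is.null(wrist_xyz)) return(NULL)
  net_w <- sqrt(wrist_xyz$x^2 + wrist_xyz$y^2 + wrist_xyz$z^2)
  list(ACC_net_w_mean = mean(net_w), ACC_net_w_std = pop_sd(net_w),
       ACC_x_mean = mean(wrist_xyz$x), ACC_x_min = min(wrist_xyz$x),
       ACC_x_C_std = pop_sd(chest_xyz$x))
}

#' Skin-temperature window features
#'
#' @param series temperature samples in the window, degrees C.
#' @return `TEMP_mean`, or `NULL` for an empty window.
#' @export
temp_features <- function(series) {
  if (length(series) == 0 || !any(is.finite(series))) return(NULL)
  list(TEMP_mean = mean(series))
}

slice_channel <- function(ch, start_s, end_s) {
  i0 <- floor(start_s * ch$fs) + 1L
  i1 <- min(length(ch$samples), floor(end_s * ch$fs))
  if (i0 > i1) return(numeric(0))
  ch$samples[i0:i1]
}

#' Extract a labelled feature table from a recording
#'
#' Slides windows of `spec$length_s` seconds every `spec$shift_s` seconds
#' across the recording, runs every per-modality extractor, and attaches the
#' binary anxiety label from the STAI score of the annotation covering the
#' window midpoint (and the generator-side truth for validation). Windows
#' where any extractor signals a drop, or whose midpoint is unannotated, are
#' dropped and counted.
#'
#' @param recording a `multimodal_recording`.
#' @param spec a [window_spec()].
#' @param label a [label_spec()] used to dichotomise STAI scores.
#' @param peaks optional precomputed [peak_result()] for the ECG channel;
#'   detected with [ampd_detect()] when `NULL`.
#' @param subset subset tag stored per row (default `NA`).
#' @return An object of class `feature_table`: `rows` (a data frame with id
#'   columns, the 21 features, `label`, `truth`, `subset`), the window spec,
#'   drop counts, and the feature-to-modality map.
#' @export
extract_windows <- function(recording, spec = window_spec(),
                            label = label_spec(), peaks = NULL,
                            subset = NA_character_) {
  chans <- recording$channels
  duration <- length(chans$ECG$samples) / chans$ECG$fs
  if (spec$length_s > duration) {
    stop("window longer than the recording", call. = FALSE)
  }
  if (is.null(peaks)) {
    peaks <- ampd_detect(chans$ECG$samples, chans$ECG$fs)
  }
  n_win <- floor((duration - spec$length_s) / spec$shift_s) + 1
  drops <- c(ECG = 0L, RESP = 0L, EDA = 0L, BVP = 0L, TEMP = 0L,
             ACC = 0L, unlabelled = 0L)
  rows <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    start_s <- (w - 1) * spec$shift_s
    end_s <- start_s + spec$length_s
    mid <- start_s + spec$length_s / 2
    ann <- NULL
    for (a in recording$annotations) {
      if (mid >= a$start_s && mid < a$end_s) { ann <- a; break }
    }
    if (is.null(ann)) { drops[["unlabelled"]] <- drops[["unlabelled"]] + 1L; next }
    f_ecg <- ecg_features(peaks, start_s, end_s)
    if (is.null(f_ecg)) { drops[["ECG"]] <- drops[["ECG"]] + 1L; next }
    f_resp <- resp_features(slice_channel(chans$RESP, start_s, end_s),
                            chans$RESP$fs)
    if (is.null(f_resp)) { drops[["RESP"]] <- drops[["RESP"]] + 1L; next }
    f_eda <- eda_features(slice_channel(chans$EDA, start_s, end_s))
    if (is.null(f_eda)) { drops[["EDA"]] <- drops[["EDA"]] + 1L; next }
    f_bvp <- bvp_features(slice_channel(chans$BVP, start_s, end_s),
                          chans$BVP$fs)
    if (is.null(f_bvp)) { drops[["BVP"]] <- drops[["BVP"]] + 1L; next }
    f_temp <- temp_features(slice_channel(chans$TEMP, start_s, end_s))
    if (is.null(f_temp)) { drops[["TEMP"]] <- drops[["TEMP"]] + 1L; next }
    f_acc <- acc_features(
      lapply(list(x = chans$ACC_C_x, y = chans$ACC_C_y, z = chans$ACC_C_z),
             slice_channel, start_s, end_s),
      lapply(list(x = chans$ACC_w_x, y = chans$ACC_w_y, z = chans$ACC_w_z),
             slice_channel, start_s, end_s))
    if (is.null(f_acc)) { drops[["ACC"]] <- drops[["ACC"]] + 1L; next }
    feats <- c(f_ecg, f_resp, f_eda, f_bvp, f_temp, f_acc)
    if (any(!vapply(feats, is.finite, logical(1)))) {
      drops[["unlabelled"]] <- drops[["unlabelled"]] + 1L
      next
    }
    rows[[w]] <- c(list(subject_id = recording$subject_id,
                        window_start_s = start_s),
                   feats,
                   list(label = label_from_stai(ann$stai_y6, label),
                        truth = as.integer(ann$anxious_truth),
                        subset = subset))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows) > 0) {
    do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  } else {
    empty <- stats::setNames(
      rep(list(numeric(0)), length(feature_modality_map())),
      names(feature_modality_map()))
    do.call(data.frame, c(list(subject_id = character(0),
                               window_start_s = numeric(0)),
                          empty,
                          list(label = integer(0), truth = integer(0),
                               subset = character(0))))
  }
  feature_table(df, window = spec, drop_counts = as.list(drops))
}

#' Feature table container
#'
#' @param rows data frame with id columns, canonical features, `label`,
#'   `truth` and `subset`.
#' @param window the [window_spec()] used.
#' @param drop_counts named list of per-modality dropped-window counts.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(rows, window = window_spec(), drop_counts = list()) {
  needed <- names(feature_modality_map())
  miss <- setdiff(needed, names(rows))
  if (length(miss) > 0) {
    stop("feature table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(list(rows = rows, window = window, drop_counts = drop_counts,
                 feature_to_modality = feature_modality_map()),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d windows, %d features, %d anxious (%.1f%%)\n",
              nrow(x$rows), length(x$feature_to_modality),
              sum(x$rows$label), 100 * mean(x$rows$label)))
  invisible(x)
}

#' Extract and pool feature tables for a whole cohort
#'
#' @param cohort list of `multimodal_recording`s from [generate_cohort()].
#' @param spec a [window_spec()].
#' @param label a [label_spec()].
#' @param subset subset tag stored per row.
#' @return A pooled `feature_table`.
#' @export
cohort_features <- function(cohort, spec = window_spec(),
                            label = label_spec(), subset = NA_character_) {
  tabs <- lapply(cohort, extract_windows, spec = spec, label = label,
                 subset = subset)
  rows <- do.call(rbind, lapply(tabs, `[[`, "rows"))
  drops <- Reduce(function(a, b) Map(`+`, a, b),
                  lapply(tabs, `[[`, "drop_counts"))
  feature_table(rows, window = spec, drop_counts = drops)
}
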