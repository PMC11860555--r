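## Signal-conditioning steps applied between raw channels and feature
## extraction: zero-phase Butterworth low-pass filtering, Hampel outlier
## removal, min-max normalisation, decimation, mean imputation / segment
## dropping, and SNR-calibrated Gaussian noise injection.

#' Zero-phase Butterworth low-pass filter
#'
#' Designs an order-`order` digital Butterworth low-pass filter and applies
#' it forward and backward (zero phase, squared magnitude response). The
#' series is extended at both ends by odd reflection before filtering to
#' suppress edge transients, then trimmed back to its original length.
#'
#' @param series numeric vector.
#' @param fs sampling rate, Hz.
#' @param cutoff -3 dB cutoff frequency, Hz (must be below Nyquist).
#' @param order filter order per pass (default 4).
#' @return Filtered series, same length as the input.
#' @export
lowpass_butterworth <- function(series, fs, cutoff, order = 4) {
  stopifnot_positive(fs, "fs")
  stopifnot_positive(cutoff, "cutoff")
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  if (cutoff >= fs / 2) {
    stop("`cutoff` must be below the Nyquist frequency fs/2", call. = FALSE)
  }
  n <- length(series)
  ba <- signal::butter(order, cutoff / (fs / 2), type = "low")
  pad <- min(n - 1, max(3 * (order + 1), ceiling(3 * fs / cutoff)))
  if (pad < 1) return(series)
  front <- 2 * series[1] - series[(pad + 1):2]
  back <- 2 * series[n] - series[(n - 1):(n - pad)]
  ext <- c(front, series, back)
  ## steady-state initial conditions (DC gain 1), scipy-filtfilt style
  run <- function(x) {
    as.numeric(signal::filter(ba$b, ba$a, x,
                              init.x = rep(x[1], length(ba$b) - 1),
                              init.y = rep(x[1], length(ba$a) - 1)))
  }
  y <- rev(run(rev(run(ext))))
  y[(pad + 1):(pad + n)]
}

#' Hampel outlier removal
#'
#' Marks points lying more than `n_mad` scaled median absolute deviations
#' from the rolling median as missing (`NA`). Constant windows (MAD 0) never
#' flag points beyond exact-duplicate tolerance, so degenerate segments pass
#' through unchanged.
#'
#' @param series numeric vector.
#' @param window odd rolling window length in samples (>= 3).
#' @param n_mad outlier threshold in scaled-MAD units (default 4).
#' @return A list: `series` with outliers set to `NA`, and `report`, a
#'   `cleaning_report` with the replacement count.
#' @export
remove_outliers <- function(series, window = 7, n_mad = 4) {
  if (window < 3 || window %% 2 == 0) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  k <- (window - 1) / 2
  idx <- integer(0)
  if (length(series) >= window) {
    h <- pracma::hampel(series, k = k, t0 = n_mad)
    idx <- h$ind
  }
  out <- series
  out[idx] <- NA_real_
  list(series = out,
       report = cleaning_report(n_outliers_replaced = length(idx)))
}

#' Min-max normalisation to \[0, 1\]
#'
#' @param series numeric vector with at least two distinct finite values.
#'   Missing values propagate.
#' @return `(x - min) / (max - min)`.
#' @export
minmax_normalize <- function(series) {
  fin <- series[is.finite(series)]
  if (length(unique(fin)) < 2) {
    stop("degenerate range: series needs >= 2 distinct finite values",
         call. = FALSE)
  }
  (series - min(fin)) / (max(fin) - min(fin))
}

#' Downsample a series with anti-alias filtering
#'
#' Applies a zero-phase Butterworth anti-alias filter at 0.45 times the
#' target rate, then resamples onto the output time grid (exact decimation
#' for integer rate ratios, linear interpolation otherwise). The output has
#' exactly `floor(n * fs_out / fs_in)` samples.
#'
#' @param series numeric vector.
#' @param fs_in,fs_out input and output sampling rates, Hz
#'   (`fs_out <= fs_in`).
#' @return Downsampled series.
#' @export
downsample <- function(series, fs_in, fs_out) {
  stopifnot_positive(fs_in, "fs_in")
  stopifnot_positive(fs_out, "fs_out")
  if (fs_out > fs_in) {
    stop("`fs_out` must not exceed `fs_in`", call. = FALSE)
  }
  if (fs_out == fs_in) return(series)
  n <- length(series)
  y <- lowpass_butterworth(series, fs_in, cutoff = 0.45 * fs_out, order = 4)
  m <- floor(n * fs_out / fs_in)
  t_out <- (seq_len(m) - 1) / fs_out
  ratio <- fs_in / fs_out
  if (abs(ratio - round(ratio)) < 1e-9) {
    y[1 + (seq_len(m) - 1) * round(ratio)]
  } else {
    stats::approx(x = (seq_len(n) - 1) / fs_in, y = y, xout = t_out)$y
  }
}

#' Cleaning report
#'
#' @param n_outliers_replaced count of points marked missing by the outlier
#'   rule.
#' @param n_imputed count of missing points replaced by the segment mean.
#' @param dropped whether the segment was dropped.
#' @param missing_frac fraction of missing points before imputation.
#' @return An object of class `cleaning_report`.
#' @export
cleaning_report <- function(n_outliers_replaced = 0L, n_imputed = 0L,
                            dropped = FALSE, missing_frac = 0) {
  structure(list(n_outliers_replaced = as.integer(n_outliers_replaced),
                 n_imputed = as.integer(n_imputed),
                 dropped = isTRUE(dropped),
                 missing_frac = missing_frac),
            class = "cleaning_report")
}

#' Mean imputation with a segment-drop rule
#'
#' If the missing fraction of the segment is at most `max_missing_frac`,
#' missing points are replaced by the mean of the observed points; otherwise
#' the segment is flagged dropped (a fully missing segment is always
#' dropped). Imputation preserves the observed-sample mean exactly.
#'
#' @param series numeric vector, possibly containing `NA`.
#' @param max_missing_frac drop threshold in (0, 1); default 0.2.
#' @return A list: `series` (imputed, or unchanged when dropped) and
#'   `report` (a `cleaning_report`).
#' @export
impute_or_drop <- function(series, max_missing_frac = 0.2) {
  if (max_missing_frac <= 0 || max_missing_frac >= 1) {
    stop("`max_missing_frac` must lie in (0, 1)", call. = FALSE)
  }
  miss <- !is.finite(series)
  frac <- mean(miss)
  if (frac == 0) {
    return(list(series = series, report = cleaning_report(missing_frac = 0)))
  }
  if (frac > max_missing_frac || all(miss)) {
    return(list(series = series,
                report = cleaning_report(dropped = TRUE, missing_frac = frac)))
  }
  out <- series
  out[miss] <- mean(series[!miss])
  list(series = out,
       report = cleaning_report(n_imputed = sum(miss), missing_frac = frac))
}

#' Inject Gaussian noise at a target signal-to-noise ratio
#'
#' Adds white Gaussian noise with variance `var(series) / snr_linear`, so the
#' ratio of signal power to injected noise power equals `snr_linear` (a
#' linear power ratio; values below 1 mean the noise dominates).
#'
#' @param series non-constant numeric vector.
#' @param snr_linear target linear SNR (> 0); `Inf` returns the series
#'   unchanged.
#' @param seed integer seed (reproducible injection).
#' @return Noisy series of the same length.
#' @export
add_gaussian_noise <- function(series, snr_linear, seed = 1) {
  if (!is.numeric(snr_linear) || length(snr_linear) != 1L || snr_linear <= 0) {
    stop("`snr_linear` must be a single positive ratio", call. = FALSE)
  }
  if (is.infinite(snr_linear)) return(series)
  v <- stats::var(series)
  if (!is.finite(v) || v == 0) {
    stop("`series` must be non-constant to define an SNR", call. = FALSE)
  }
  local_seed(seed, series + rnorm(length(series), 0, sqrt(v / snr_linear)))
}

#' Apply the standard channel conditioning to a recording
#'
#' EDA channels are low-pass filtered at 5 Hz and accelerometer channels at
#' 13 Hz (zero-phase Butterworth, order 4); other channels pass through
#' unfiltered. Filtering a channel sampled at or below twice the cutoff is
#' skipped (already band-limited by the device).
#'
#' @param recording a `multimodal_recording`.
#' @param eda_cutoff,acc_cutoff cutoff frequencies, Hz.
#' @return The conditioned recording.
#' @export
preprocess_recording <- function(recording, eda_cutoff = 5, acc_cutoff = 13) {
  for (nm in names(recording$channels)) {
    ch <- recording$channels[[nm]]
    cutoff <- if (nm == "EDA") eda_cutoff
      else if (startsWith(nm, "ACC")) acc_cutoff else NA
    if (!is.na(cutoff) && ch$fs > 2 * cutoff) {
      recording$channels[[nm]]$samples <-
        lowpass_butterworth(ch$samples, ch$fs, cutoff)
    }
  }
  recording
}

#' Add channel noise to a whole recording at a target SNR
#'
#' @param recording a `multimodal_recording`.
#' @param snr_linear target linear SNR applied per channel.
#' @param seed integer seed.
#' @param channels channel names to perturb (default: all).
#' @return The noise-augmented recording.
#' @export
noise_augment_recording <- function(recording, snr_linear, seed = 1,
                                    channels = names(recording$channels)) {
  for (nm in channels) {
    ch <- recording$channels[[nm]]
    if (stats::var(ch$samples) > 0) {
      recording$channels[[nm]]$samples <-
        add_gaussian_noise(ch$samples, snr_linear,
                           seed = derive_seed(seed, nm))
    }
  }
  recording
}
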