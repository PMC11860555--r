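## Channel generators. All are template-level renderings: the aim is that the
## downstream peak/feature logic sees realistic rates, variability and
## asymmetries with known ground truth, not that waveform morphology is
## clinically faithful.

## i.i.d. normal RR intervals truncated to [0.3, 2] s (rejection sampling)
draw_rr <- function(n, mean_rr, sdnn) {
  if (sdnn <= 0) return(rep(mean_rr, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean_rr, sdnn)
    out <- c(out, x[x >= 0.3 & x <= 2.0])
  }
  out[seq_len(n)]
}

## beat train covering (0, duration]; first beat centred in its RR interval
draw_beats <- function(duration_s, hr_bpm, sdnn) {
  mean_rr <- 60 / hr_bpm
  n_max <- ceiling(duration_s / max(mean_rr - 4 * sdnn, 0.3)) + 2L
  rr <- draw_rr(n_max, mean_rr, sdnn)
  beats <- cumsum(rr) - rr[1] / 2
  beats[beats <= duration_s]
}

## add Gaussian bumps amp*exp(-(t-b)^2/(2 sigma^2)) at times `beats`
render_pulses <- function(n, fs, beats, amp, sigma) {
  x <- numeric(n)
  half <- ceiling(5 * sigma * fs)
  for (b in beats) {
    c_idx <- round(b * fs) + 1
    idx <- max(1, c_idx - half):min(n, c_idx + half)
    if (length(idx) == 0 || idx[1] > n) next
    t_rel <- (idx - 1) / fs - b
    x[idx] <- x[idx] + amp * exp(-t_rel^2 / (2 * sigma^2))
  }
  x
}

effective_hr <- function(profile, state) {
  profile$baseline_hr + if (isTRUE(state)) profile$anxiety_deltas$hr_delta else 0
}

effective_sdnn <- function(profile, state) {
  max(0, profile$sdnn +
        if (isTRUE(state)) profile$anxiety_deltas$sdnn_delta else 0)
}

#' Generate a synthetic single-lead ECG
#'
#' RR intervals are drawn i.i.d. from a normal distribution (mean `60/hr`,
#' sd `sdnn`) truncated to \[0.3, 2\] s; each beat is rendered as a narrow
#' Gaussian QRS bump, on top of sinusoidal baseline wander (0.2 Hz) and white
#' measurement noise. The exact beat times are returned as ground truth.
#'
#' @param profile a [subject_profile()].
#' @param duration_s record length, seconds (> 0).
#' @param fs sampling rate, Hz (>= 64).
#' @param state logical; `TRUE` applies the profile's anxious-state shifts.
#' @param seed integer seed.
#' @param noise_sd white measurement noise sd (signal units; QRS amplitude 1).
#' @param wander_amp amplitude of the 0.2 Hz baseline wander.
#' @param qrs_sigma Gaussian QRS width parameter, seconds (~40 ms bump).
#' @return A list with `series`, `true_beats_s`, and `fs`.
#' @export
generate_ecg <- function(profile, duration_s, fs = 256, state = FALSE,
                         seed = 1, noise_sd = 0.02, wander_amp = 0.1,
                         qrs_sigma = 0.015) {
  stopifnot_positive(duration_s, "duration_s")
  if (fs < 64) stop("`fs` must be >= 64 Hz for ECG", call. = FALSE)
  hr <- effective_hr(profile, state)
  stopifnot_positive(hr, "heart rate")
  sdnn <- effective_sdnn(profile, state)
  local_seed(seed, {
    beats <- draw_beats(duration_s, hr, sdnn)
    n <- n_samples(duration_s, fs)
    t <- sample_times(n, fs)
    x <- render_pulses(n, fs, beats, amp = 1, sigma = qrs_sigma)
    if (wander_amp > 0) {
      phase <- runif(1, 0, 2 * pi)
      x <- x + wander_amp * sin(2 * pi * 0.2 * t + phase)
    }
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    list(series = x, true_beats_s = beats, fs = fs)
  })
}

#' Generate a synthetic electrodermal activity (EDA) series
#'
#' Tonic level plus slow sinusoidal drift plus phasic skin-conductance
#' responses (SCRs) arriving as a Poisson process; each SCR is a
#' bi-exponential pulse (1 s rise, 4 s decay, ~0.3 uS amplitude). The series
#' is clipped at zero (conductance cannot be negative).
#'
#' @inheritParams generate_ecg
#' @param fs sampling rate, Hz (>= 2).
#' @param noise_sd white noise sd, microsiemens.
#' @param drift_amp amplitude of the slow tonic drift, microsiemens.
#' @param scr_amp nominal SCR amplitude, microsiemens.
#' @return Numeric series, microsiemens, with the ground-truth SCR onset
#'   times attached as attribute `scr_onsets_s`.
#' @export
generate_eda <- function(profile, duration_s, fs = 4, state = FALSE, seed = 1,
                         noise_sd = 0.01, drift_amp = 0.05, scr_amp = 0.3) {
  stopifnot_positive(duration_s, "duration_s")
  if (fs < 2) stop("`fs` must be >= 2 Hz for EDA", call. = FALSE)
  rate <- profile$scr_rate +
    if (isTRUE(state)) profile$anxiety_deltas$scr_delta else 0
  if (rate < 0) stop("SCR rate must be >= 0", call. = FALSE)
  local_seed(seed, {
    n <- n_samples(duration_s, fs)
    t <- sample_times(n, fs)
    x <- rep(profile$eda_tonic, n)
    if (drift_amp > 0) {
      phase <- runif(1, 0, 2 * pi)
      x <- x + drift_amp * sin(2 * pi * 0.004 * t + phase)
    }
    n_scr <- rpois(1, rate * duration_s / 60)
    onsets <- numeric(0)
    if (n_scr > 0) {
      onsets <- sort(runif(n_scr, 0, duration_s))
      amps <- scr_amp * runif(n_scr, 0.7, 1.3)
      ## bi-exponential kernel, peak normalised to 1
      peak_t <- log(4) / (1 - 1 / 4)
      peak_v <- exp(-peak_t / 4) - exp(-peak_t)
      for (j in seq_len(n_scr)) {
        idx <- which(t >= onsets[j] & t <= onsets[j] + 20)
        tr <- t[idx] - onsets[j]
        x[idx] <- x[idx] + amps[j] * (exp(-tr / 4) - exp(-tr)) / peak_v
      }
    }
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    x <- pmax(x, 0)
    attr(x, "scr_onsets_s") <- onsets   # generator-side ground truth
    x
  })
}

#' Generate a synthetic respiration series
#'
#' Piecewise-sinusoidal breath cycles. Each cycle lasts `60/resp_rate`
#' seconds (with multiplicative jitter); the inhale occupies
#' `ie_ratio / (1 + ie_ratio)` of the cycle (trough-to-peak rising half-wave)
#' and the exhale the remainder (falling half-wave), so inhale/exhale
#' asymmetry is recoverable from zero-crossing/peak segmentation.
#'
#' @inheritParams generate_ecg
#' @param fs sampling rate, Hz.
#' @param amp breath amplitude (arbitrary respiration-belt units).
#' @param jitter_sd multiplicative sd of cycle-duration jitter (0 = metronomic).
#' @param noise_sd additive white noise sd.
#' @return Numeric series, zero-mean over whole cycles.
#' @export
generate_resp <- function(profile, duration_s, fs = 128, state = FALSE,
                          seed = 1, amp = 0.5, jitter_sd = 0.03,
                          noise_sd = 0.01) {
  stopifnot_positive(duration_s, "duration_s")
  rate <- profile$resp_rate +
    if (isTRUE(state)) profile$anxiety_deltas$resp_delta else 0
  stopifnot_positive(rate, "respiration rate")
  if (profile$ie_ratio <= 0) stop("`ie_ratio` must be > 0", call. = FALSE)
  local_seed(seed, {
    n <- n_samples(duration_s, fs)
    t <- sample_times(n, fs)
    x <- numeric(n)
    mean_cycle <- 60 / rate
    inh_frac <- profile$ie_ratio / (1 + profile$ie_ratio)
    t0 <- 0
    while (t0 < duration_s) {
      cyc <- mean_cycle * max(0.3, 1 + if (jitter_sd > 0) rnorm(1, 0, jitter_sd) else 0)
      t_in <- cyc * inh_frac
      idx <- which(t >= t0 & t < t0 + cyc)
      if (length(idx) > 0) {
        s <- t[idx] - t0
        inh <- s < t_in
        y <- numeric(length(s))
        y[inh] <- -cos(pi * s[inh] / t_in)
        y[!inh] <- cos(pi * (s[!inh] - t_in) / (cyc - t_in))
        x[idx] <- amp * y
      }
      t0 <- t0 + cyc
    }
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    x
  })
}

#' Generate a synthetic 3-axis accelerometer recording
#'
#' A gravity-dominated constant vector plus an activity component: seated is
#' near-static white noise, standing adds slow postural sway, walking adds a
#' ~2 Hz step oscillation of ~0.3 g, and `"variable"` alternates between the
#' three regimes on random dwell times.
#'
#' @param activity one of `"seated"`, `"standing"`, `"walking"`, `"variable"`.
#' @param duration_s record length, seconds.
#' @param fs sampling rate, Hz (>= 16).
#' @param seed integer seed.
#' @param device `"chest"` (gravity on z) or `"wrist"` (gravity tilted on x).
#' @param noise_sd white accelerometer noise sd, g.
#' @param walk_freq step frequency, Hz.
#' @param walk_amp step oscillation amplitude, g.
#' @return A list with numeric series `x`, `y`, `z` (units of g).
#' @export
generate_acc <- function(activity, duration_s, fs = 64, seed = 1,
                         device = c("chest", "wrist"), noise_sd = 0.01,
                         walk_freq = 2, walk_amp = 0.3) {
  device <- match.arg(device)
  stopifnot_positive(duration_s, "duration_s")
  if (fs < 16) stop("`fs` must be >= 16 Hz for ACC", call. = FALSE)
  activities <- c("seated", "standing", "walking", "variable")
  if (!activity %in% activities) {
    stop("unknown activity label: ", activity, call. = FALSE)
  }
  gravity <- if (device == "chest") c(0, 0, 1) else
    c(cos(20 * pi / 180), 0, sin(20 * pi / 180))
  local_seed(seed, {
    n <- n_samples(duration_s, fs)
    t <- sample_times(n, fs)
    regime <- if (activity == "variable") {
      ## random dwell times, mean 30 s, cycling through sampled regimes
      lab <- character(n)
      t0 <- 0
      while (t0 < duration_s) {
        dwell <- max(5, stats::rexp(1, 1 / 30))
        lab[t >= t0 & t < t0 + dwell] <-
          sample(c("seated", "standing", "walking"), 1)
        t0 <- t0 + dwell
      }
      lab
    } else rep(activity, n)
    xyz <- matrix(rep(gravity, each = n), ncol = 3)
    sd_axis <- ifelse(regime == "seated", noise_sd,
                      ifelse(regime == "standing", 2 * noise_sd, 4 * noise_sd))
    for (a in 1:3) {
      if (noise_sd > 0) xyz[, a] <- xyz[, a] + rnorm(n, 0, sd_axis)
    }
    stand <- regime == "standing"
    if (any(stand)) {
      phase <- runif(1, 0, 2 * pi)
      sway <- 0.02 * sin(2 * pi * 0.3 * t + phase)
      xyz[stand, 1] <- xyz[stand, 1] + sway[stand]
    }
    walk <- regime == "walking"
    if (any(walk)) {
      phase <- runif(2, 0, 2 * pi)
      vert <- which.max(abs(gravity))
      lat <- if (vert == 1) 2 else 1
      step <- walk_amp * sin(2 * pi * walk_freq * t + phase[1])
      lat_osc <- 0.1 * sin(2 * pi * walk_freq / 2 * t + phase[2])
      xyz[walk, vert] <- xyz[walk, vert] + step[walk]
      xyz[walk, lat] <- xyz[walk, lat] + lat_osc[walk]
    }
    list(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
}

#' Generate a synthetic distal skin-temperature series
#'
#' Baseline temperature (shifted in the anxious state, where peripheral
#' vasoconstriction lowers distal skin temperature) plus a Gaussian random
#' walk drift and measurement noise.
#'
#' @inheritParams generate_ecg
#' @param fs sampling rate, Hz.
#' @param drift_sd per-sample sd of the random-walk drift, degrees C.
#' @param noise_sd measurement noise sd, degrees C.
#' @return Numeric series, degrees C.
#' @export
generate_temp <- function(profile, duration_s, fs = 4, state = FALSE,
                          seed = 1, drift_sd = 0.002, noise_sd = 0.01) {
  stopifnot_positive(duration_s, "duration_s")
  stopifnot_positive(fs, "fs")
  base <- profile$temp_base +
    if (isTRUE(state)) profile$anxiety_deltas$temp_delta else 0
  local_seed(seed, {
    n <- n_samples(duration_s, fs)
    x <- rep(base, n)
    if (drift_sd > 0) x <- x + cumsum(rnorm(n, 0, drift_sd))
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    x
  })
}

#' Generate a synthetic blood volume pulse (BVP) series
#'
#' A pulse train at the subject's RR sequence, each pulse rendered as a
#' systolic peak plus a smaller dicrotic bump. The dominant spectral
#' frequency equals the heart rate in Hz.
#'
#' @inheritParams generate_ecg
#' @param fs sampling rate, Hz.
#' @param beats_s optional beat times to reuse (e.g. the ECG ground truth,
#'   delayed by pulse transit time); if `NULL`, a fresh RR sequence is drawn.
#' @param noise_sd white noise sd.
#' @return A list with `series`, `true_beats_s`, and `fs`.
#' @export
generate_bvp <- function(profile, duration_s, fs = 64, state = FALSE,
                         seed = 1, beats_s = NULL, noise_sd = 0.02) {
  stopifnot_positive(duration_s, "duration_s")
  stopifnot_positive(fs, "fs")
  hr <- effective_hr(profile, state)
  stopifnot_positive(hr, "heart rate")
  sdnn <- effective_sdnn(profile, state)
  local_seed(seed, {
    beats <- if (is.null(beats_s)) draw_beats(duration_s, hr, sdnn) else
      beats_s[beats_s > 0 & beats_s <= duration_s]
    n <- n_samples(duration_s, fs)
    x <- render_pulses(n, fs, beats, amp = 1, sigma = 0.08) +
      render_pulses(n, fs, beats + 0.35, amp = 0.35, sigma = 0.06)
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    list(series = x, true_beats_s = beats, fs = fs)
  })
}

#' Assemble a full multimodal session from a condition plan
#'
#' Generates every channel interval-by-interval (physiology following each
#' interval's anxious/non-anxious truth and implied activity), concatenates
#' them, samples a STAI Y6 score per interval (relaxation intervals score
#' below the anxiety cutoff, induction intervals at or above it, crossing
#' sides with probability `label_noise`), and carries the annotations and
#' ground-truth beat times through.
#'
#' @param profile a [subject_profile()].
#' @param plan list of [condition_interval()]s, ordered, non-overlapping,
#'   starting at 0; whole-second bounds recommended so sample counts are exact.
#' @param seed integer seed.
#' @param label_noise probability that an interval's STAI score falls on the
#'   wrong side of the cutoff (default 0.05).
#' @param noise_scale multiplier on all channel measurement-noise sds (the
#'   in-the-wild subset uses > 1).
#' @param rates named sampling-rate vector, see [channel_rates()].
#' @param subject_id opaque identifier stored in the recording.
#' @return An object of class `multimodal_recording`: `channels` (named list
#'   of `samples`/`fs`/`device`), `annotations`, `true_beats_s`, `subject_id`.
#' @export
generate_session <- function(profile, plan, seed = 1, label_noise = 0.05,
                             noise_scale = 1, rates = channel_rates(),
                             subject_id = "S1") {
  validate_plan(plan)
  if (abs(plan[[1]]$start_s) > 1e-9) {
    stop("session plan must start at 0 s", call. = FALSE)
  }
  devices <- channel_devices()
  chans <- stats::setNames(vector("list", length(rates)), names(rates))
  for (nm in names(rates)) chans[[nm]] <- list()
  beats_all <- numeric(0)
  annotations <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    iv <- plan[[i]]
    dur <- iv$end_s - iv$start_s
    state <- iv$anxious_truth
    activity <- condition_activity(iv$condition)
    s_ecg <- derive_seed(seed, i, "ECG")
    ecg <- generate_ecg(profile, dur, rates[["ECG"]], state, s_ecg,
                        noise_sd = 0.02 * noise_scale)
    beats_all <- c(beats_all, iv$start_s + ecg$true_beats_s)
    chans$ECG[[i]] <- ecg$series
    chans$RESP[[i]] <- generate_resp(profile, dur, rates[["RESP"]], state,
                                     derive_seed(seed, i, "RESP"),
                                     noise_sd = 0.01 * noise_scale)
    acc_c <- generate_acc(activity, dur, rates[["ACC_C_x"]],
                          derive_seed(seed, i, "ACCC"), device = "chest",
                          noise_sd = 0.01 * noise_scale)
    chans$ACC_C_x[[i]] <- acc_c$x
    chans$ACC_C_y[[i]] <- acc_c$y
    chans$ACC_C_z[[i]] <- acc_c$z
    acc_w <- generate_acc(activity, dur, rates[["ACC_w_x"]],
                          derive_seed(seed, i, "ACCW"), device = "wrist",
                          noise_sd = 0.015 * noise_scale)
    chans$ACC_w_x[[i]] <- acc_w$x
    chans$ACC_w_y[[i]] <- acc_w$y
    chans$ACC_w_z[[i]] <- acc_w$z
    ## BVP reuses the ECG beat train, delayed by a 0.25 s pulse transit time
    bvp <- generate_bvp(profile, dur, rates[["BVP"]], state,
                        derive_seed(seed, i, "BVP"),
                        beats_s = ecg$true_beats_s + 0.25,
                        noise_sd = 0.02 * noise_scale)
    chans$BVP[[i]] <- bvp$series
    chans$EDA[[i]] <- generate_eda(profile, dur, rates[["EDA"]], state,
                                   derive_seed(seed, i, "EDA"),
                                   noise_sd = 0.01 * noise_scale)
    chans$TEMP[[i]] <- generate_temp(profile, dur, rates[["TEMP"]], state,
                                     derive_seed(seed, i, "TEMP"),
                                     noise_sd = 0.01 * noise_scale)
    ## STAI Y6: calm side 6..10, anxious side 11..24 (clustered low)
    stai <- local_seed(derive_seed(seed, i, "STAI"), {
      side_anx <- xor(state, runif(1) < label_noise)
      if (side_anx) sample(11:18, 1) else sample(6:10, 1)
    })
    annotations[[i]] <- condition_interval(iv$start_s, iv$end_s, iv$condition,
                                           stai_y6 = stai,
                                           anxious_truth = state)
  }
  channels <- stats::setNames(vector("list", length(rates)), names(rates))
  for (nm in names(rates)) {
    channels[[nm]] <- list(samples = unlist(chans[[nm]], use.names = FALSE),
                           fs = unname(rates[[nm]]),
                           device = unname(devices[[nm]]))
  }
  structure(list(channels = channels, annotations = annotations,
                 true_beats_s = beats_all, subject_id = subject_id,
                 profile = profile, seed = as.integer(seed)),
            class = "multimodal_recording")
}

#' @export
print.multimodal_recording <- function(x, ...) {
  dur <- length(x$channels$ECG$samples) / x$channels$ECG$fs
  cat(sprintf("<multimodal_recording> subject %s, %.0f s, %d channels, %d intervals\n",
              x$subject_id, dur, length(x$channels), length(x$annotations)))
  invisible(x)
}

## block plan builders --------------------------------------------------------

## split duration into whole-second blocks by fractions (last block absorbs
## rounding remainder)
split_blocks <- function(duration_s, fracs) {
  d <- floor(duration_s * fracs)
  d[length(d)] <- duration_s - sum(d[-length(d)])
  d
}

plan_calibration <- function(duration_s) {
  durs <- split_blocks(duration_s, c(0.29, 0.21, 0.29, 0.21))
  conds <- c("relaxation", "cold_pressor", "relaxation", "cold_pressor")
  edges <- cumsum(c(0, durs))
  lapply(seq_along(conds), function(i) {
    condition_interval(edges[i], edges[i + 1], conds[i])
  })
}

plan_in_lab <- function(duration_s) {
  durs <- split_blocks(duration_s, c(0.30, 0.14, 0.29, 0.14, 0.13))
  conds <- c("relaxation", "tsst", "relaxation", "stroop_seated",
             "stroop_walking")
  edges <- cumsum(c(0, durs))
  lapply(seq_along(conds), function(i) {
    condition_interval(edges[i], edges[i + 1], conds[i])
  })
}

## in-the-wild: anxious time is allocated exactly (up to 1 s rounding) as
## `frac` of the session, split across blocks in a seeded random order
plan_wild <- function(duration_s, frac, seed) {
  anx_total <- max(1, round(duration_s * frac))
  calm_total <- duration_s - anx_total
  anx_durs <- if (anx_total >= 120) {
    c(floor(anx_total / 2), anx_total - floor(anx_total / 2))
  } else anx_total
  n_calm <- min(4, max(2, floor(calm_total / 60)))
  calm_durs <- split_blocks(calm_total, rep(1 / n_calm, n_calm))
  durs <- c(anx_durs, calm_durs)
  states <- c(rep(TRUE, length(anx_durs)), rep(FALSE, length(calm_durs)))
  ord <- local_seed(seed, sample(seq_along(durs)))
  durs <- durs[ord]
  states <- states[ord]
  edges <- cumsum(c(0, durs))
  lapply(seq_along(durs), function(i) {
    condition_interval(edges[i], edges[i + 1], "wild",
                       anxious_truth = states[i])
  })
}

#' Generate a cohort of multimodal recordings
#'
#' Builds `n_subjects` sessions following the subset's study conditions:
#' `"calibration"` alternates guided relaxation and cold-pressor blocks, all
#' seated, in a fixed environment; `"in_lab"` runs relaxation, TSST and
#' seated/walking Stroop blocks in a fixed environment; `"in_the_wild"` is
#' unconstrained time with variable activity, elevated channel noise, and
#' anxious time allocated at `wild_anxious_frac` of each session. Subject
#' physiology is drawn around population-typical values, reproducibly from
#' the config seed.
#'
#' @param config a [cohort_config()].
#' @param label_noise per-interval probability of a STAI score on the wrong
#'   side of the cutoff (default 0.05).
#' @return A list of `multimodal_recording`s.
#' @export
generate_cohort <- function(config, label_noise = 0.05) {
  if (!inherits(config, "cohort_config")) {
    stop("`config` must be a cohort_config", call. = FALSE)
  }
  dur <- round(config$session_duration_s)
  lapply(seq_len(config$n_subjects), function(s) {
    prof <- local_seed(derive_seed(config$seed, s, "profile"), {
      subject_profile(
        baseline_hr = min(95, max(55, rnorm(1, 70, 6))),
        sdnn = max(0.02, rnorm(1, 0.05, 0.008)),
        resp_rate = min(20, max(10, rnorm(1, 14, 1.5))),
        ie_ratio = runif(1, 0.6, 1.0),
        eda_tonic = runif(1, 1.5, 4),
        scr_rate = runif(1, 2, 4),
        temp_base = rnorm(1, 33, 0.5))
    })
    plan <- switch(config$subset,
                   calibration = plan_calibration(dur),
                   in_lab = plan_in_lab(dur),
                   in_the_wild = plan_wild(dur, config$wild_anxious_frac,
                                           derive_seed(config$seed, s, "plan")))
    noise_scale <- if (config$subset == "in_the_wild") 3 else 1
    generate_session(prof, plan, seed = derive_seed(config$seed, s, "sess"),
                     label_noise = label_noise, noise_scale = noise_scale,
                     subject_id = sprintf("%s_%02d", config$subset, s))
  })
}
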