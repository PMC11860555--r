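test_that("zero-variance RR gives a metronomic beat train rendered exactly", {
  prof <- subject_profile(baseline_hr = 60, sdnn = 0)
  ecg <- generate_ecg(prof, 10, 256, seed = 1, noise_sd = 0, wander_amp = 0)
  expect_length(ecg$true_beats_s, 10)
  expect_true(all(ecg$true_beats_s > 0 & ecg$true_beats_s <= 10))
  expect_equal(unique(round(diff(ecg$true_beats_s), 12)), 1.0)
  expect_length(ecg$series, 10 * 256)
})

test_that("RR draws reproduce the requested mean and spread", {
  prof <- subject_profile(baseline_hr = 60, sdnn = 0.05)
  ecg <- generate_ecg(prof, 300, 256, seed = 7)
  rr <- diff(ecg$true_beats_s)
  expect_lt(abs(mean(rr) - 1.0), 0.02)
  expect_lt(abs(sd(rr) - 0.05), 0.01)
})

test_that("anxious state shifts instantaneous heart rate by hr_delta", {
  prof <- subject_profile(baseline_hr = 60, sdnn = 0.03,
                          anxiety_deltas = list(hr_delta = 20))
  ecg <- generate_ecg(prof, 300, 256, state = TRUE, seed = 3)
  hr <- 60 / diff(ecg$true_beats_s)
  expect_lt(abs(mean(hr) - 80), 2)
})

test_that("ECG generator rejects invalid parameters", {
  prof <- subject_profile()
  expect_error(generate_ecg(prof, -1, 256), "positive")
  expect_error(generate_ecg(prof, 10, 32), "fs")
})

test_that("EDA reduces to the tonic level without SCRs, drift or noise", {
  prof <- subject_profile(eda_tonic = 2.5, scr_rate = 0)
  eda <- generate_eda(prof, 60, 4, seed = 1, noise_sd = 0, drift_amp = 0)
  expect_equal(unique(eda), 2.5)
})

test_that("SCR events arrive at the configured Poisson rate", {
  prof <- subject_profile(scr_rate = 6, eda_tonic = 2)
  counts <- vapply(1:8, function(s) {
    eda <- generate_eda(prof, 600, 4, seed = s, noise_sd = 0, drift_amp = 0)
    length(attr(eda, "scr_onsets_s"))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 60), 3 * sqrt(60))
  # and the phasic mass they deposit matches the bi-exponential kernel:
  # integral (4 - 1) s scaled to peak amplitude 0.3/0.473
  eda <- generate_eda(prof, 600, 4, seed = 3, noise_sd = 0, drift_amp = 0)
  lift <- mean(eda) - 2
  n_hat <- lift * 600 / (0.3 / 0.4724627 * 3)
  expect_lt(abs(n_hat - length(attr(eda, "scr_onsets_s"))), 10)
})

test_that("anxious state raises mean EDA via the SCR-rate delta", {
  prof <- subject_profile(scr_rate = 3,
                          anxiety_deltas = list(scr_delta = 8))
  calm <- generate_eda(prof, 300, 4, state = FALSE, seed = 11)
  anx <- generate_eda(prof, 300, 4, state = TRUE, seed = 11)
  expect_gt(mean(anx), mean(calm))
  expect_true(all(calm >= 0) && all(anx >= 0))
})

test_that("symmetric breaths give equal zero-crossing half-cycles", {
  prof <- subject_profile(resp_rate = 12, ie_ratio = 1)
  x <- generate_resp(prof, 60, 128, seed = 1, jitter_sd = 0, noise_sd = 0)
  sgn <- sign(x)
  changes <- which(diff(sgn != 0 & sgn > 0) != 0)
  half <- diff(changes) / 128
  expect_true(all(abs(half - 2.5) < 0.05))
})

test_that("inhale/exhale asymmetry and rate shift are recoverable", {
  prof <- subject_profile(resp_rate = 12, ie_ratio = 0.5,
                          anxiety_deltas = list(resp_delta = 4))
  x <- generate_resp(prof, 120, 128, seed = 2, jitter_sd = 0, noise_sd = 0)
  # breath boundaries straight from the clean waveform's extrema
  d <- diff(x)
  turns <- which(diff(sign(d)) != 0) + 1
  peaks <- turns[x[turns] > 0] / 128
  troughs <- turns[x[turns] < 0] / 128
  inhale <- vapply(seq_len(length(peaks)), function(i) {
    prev <- troughs[troughs < peaks[i]]
    if (length(prev) == 0) NA_real_ else peaks[i] - max(prev)
  }, numeric(1))
  exhale <- vapply(seq_len(length(troughs)), function(i) {
    prev <- peaks[peaks < troughs[i]]
    if (length(prev) == 0) NA_real_ else troughs[i] - max(prev)
  }, numeric(1))
  ratio <- mean(inhale, na.rm = TRUE) / mean(exhale, na.rm = TRUE)
  expect_lt(abs(ratio - 0.5) / 0.5, 0.05)

  xa <- generate_resp(prof, 120, 128, state = TRUE, seed = 2)
  fa <- resp_features(xa, 128)
  expect_lt(abs(fa$Resp_rate - 16), 1)
})

test_that("seated noiseless accelerometer sits on the 1 g gravity vector", {
  a <- generate_acc("seated", 10, 64, seed = 1, noise_sd = 0)
  net <- sqrt(a$x^2 + a$y^2 + a$z^2)
  expect_equal(unique(round(net, 12)), 1)
  expect_error(generate_acc("sprinting", 10, 64), "unknown activity")
})

test_that("walking produces a dominant non-DC spectral peak near 2 Hz", {
  a <- generate_acc("walking", 60, 64, seed = 4)
  net <- sqrt(a$x^2 + a$y^2 + a$z^2)
  net <- net - mean(net)
  p <- Mod(fft(net))^2
  freq <- (seq_along(net) - 1) * 64 / length(net)
  band <- freq > 0.3 & freq < 32
  expect_lt(abs(freq[band][which.max(p[band])] - 2), 0.2)
})

test_that("variable activity is more dynamic than seated for the same seed", {
  a_var <- generate_acc("variable", 120, 64, seed = 9)
  a_sit <- generate_acc("seated", 120, 64, seed = 9)
  sd_net <- function(a) sd(sqrt(a$x^2 + a$y^2 + a$z^2))
  expect_gt(sd_net(a_var), sd_net(a_sit))
})

test_that("temperature is constant without drift and shifts when anxious", {
  prof <- subject_profile(temp_base = 33,
                          anxiety_deltas = list(temp_delta = -0.5))
  x <- generate_temp(prof, 60, 4, seed = 1, drift_sd = 0, noise_sd = 0)
  expect_equal(unique(x), 33)
  xa <- generate_temp(prof, 60, 4, state = TRUE, seed = 1,
                      drift_sd = 0, noise_sd = 0)
  expect_equal(unique(xa), 32.5)
})

test_that("BVP dominant frequency tracks heart rate", {
  prof60 <- subject_profile(baseline_hr = 60, sdnn = 0)
  b <- generate_bvp(prof60, 60, 64, seed = 2, noise_sd = 0)
  expect_lt(abs(bvp_features(b$series, 64)$BVP_peak_freq - 1.0), 0.05)
  prof_anx <- subject_profile(baseline_hr = 60, sdnn = 0,
                              anxiety_deltas = list(hr_delta = 30))
  ba <- generate_bvp(prof_anx, 60, 64, state = TRUE, seed = 2, noise_sd = 0)
  expect_lt(abs(bvp_features(ba$series, 64)$BVP_peak_freq - 1.5), 0.05)
})

test_that("session assembly concatenates channels and scores STAI by state", {
  prof <- subject_profile()
  plan <- list(condition_interval(0, 60, "relaxation"))
  rec <- generate_session(prof, plan, seed = 1, label_noise = 0)
  expect_true(all(vapply(rec$annotations, function(a) !a$anxious_truth,
                         logical(1))))
  stai <- vapply(rec$annotations, `[[`, integer(1), "stai_y6")
  expect_true(all(stai >= 6 & stai <= 10))

  plan2 <- list(condition_interval(0, 60, "relaxation"),
                condition_interval(60, 120, "cold_pressor"),
                condition_interval(120, 180, "tsst"))
  rec2 <- generate_session(prof, plan2, seed = 2, label_noise = 0)
  stai2 <- vapply(rec2$annotations, `[[`, integer(1), "stai_y6")
  expect_lt(stai2[1], 11)       # relaxation scores low
  expect_gte(stai2[2], 11)      # cold pressor raises the score
  expect_gte(stai2[3], 11)      # TSST stays high
  for (ch in rec2$channels) {
    expect_equal(length(ch$samples), 180 * ch$fs)
  }
  expect_error(
    generate_session(prof, list(condition_interval(0, 60, "relaxation"),
                                condition_interval(30, 90, "tsst"))),
    "overlap")
})

test_that("cohorts are deterministic and follow their subset's conditions", {
  cfg <- cohort_config(2, "calibration", session_duration_s = 120, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  conds <- unlist(lapply(a, function(r)
    vapply(r$annotations, `[[`, character(1), "condition")))
  expect_true(all(conds %in% c("relaxation", "cold_pressor")))  # seated only
  expect_error(cohort_config(2, "at_home"), "unknown subset")
})

test_that("anxious deltas separate window physiology in the right directions", {
  rec <- make_small_session(seed = 31, dur_each = 240)
  ft <- extract_windows(rec, window_spec(30, 15))
  rows <- ft$rows
  calm <- rows[rows$truth == 0, ]
  anx <- rows[rows$truth == 1, ]
  expect_gte(nrow(rows), 30)
  expect_gt(t.test(anx$ECG_bpm, calm$ECG_bpm)$statistic, 2)
  expect_gt(t.test(anx$Resp_rate, calm$Resp_rate)$statistic, 2)
  expect_gt(t.test(anx$EDA_mean, calm$EDA_mean)$statistic, 2)
})

test_that("the in-the-wild anxious time fraction tracks its target", {
  cfg <- cohort_config(8, "in_the_wild", wild_anxious_frac = 0.1934,
                       session_duration_s = 600, seed = 13)
  coh <- generate_cohort(cfg)
  frac <- vapply(coh, function(r) {
    durs <- vapply(r$annotations, function(a) a$end_s - a$start_s, numeric(1))
    anx <- vapply(r$annotations, `[[`, logical(1), "anxious_truth")
    sum(durs[anx]) / sum(durs)
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.1934), 0.02)
})

test_that("recordings round-trip through the CSV + JSON format", {
  rec <- make_small_session(seed = 3, dur_each = 30)
  dir <- tempfile("rec")
  write_recording(rec, dir)
  back <- read_recording(dir)
  expect_equal(back$subject_id, rec$subject_id)
  expect_equal(back$true_beats_s, rec$true_beats_s, tolerance = 1e-6)
  expect_equal(back$channels$ECG$samples, rec$channels$ECG$samples,
               tolerance = 1e-6)
  expect_equal(length(back$annotations), length(rec$annotations))
  expect_equal(back$annotations[[2]]$condition, "cold_pressor")
  unlink(dir, recursive = TRUE)
})
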