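test_that("ECG window features are HR-series statistics", {
  # beats at 0.1, 0.85, 1.85 -> RR 0.75, 1.0 -> HR 80, 60
  pk <- peak_result(round(c(0.1, 0.85, 1.85) * 256) + 1, fs = 256)
  f <- ecg_features(pk, 0, 2)
  expect_equal(f$ECG_bpm, 70, tolerance = 0.01)
  expect_equal(f$ECG_min, 60, tolerance = 0.01)
  expect_equal(f$ECG_max, 80, tolerance = 0.01)
  expect_equal(f$ECG_std, 10, tolerance = 0.01)   # population std

  const <- peak_result(round(seq(0.5, 9.5, by = 1) * 256) + 1, fs = 256)
  fc <- ecg_features(const, 0, 10)
  expect_equal(unname(unlist(fc)), c(60, 60, 60, 0), tolerance = 1e-9)

  two <- peak_result(c(1, 257), fs = 256)
  expect_null(ecg_features(two, 0, 2))            # < 3 beats: row drop
})

test_that("respiration features recover generator timing", {
  prof <- subject_profile(resp_rate = 12, ie_ratio = 1)
  x <- generate_resp(prof, 60, 128, seed = 1, jitter_sd = 0, noise_sd = 0)
  f <- resp_features(x, 128)
  expect_lt(abs(f$Resp_rate - 12), 0.5)
  expect_lt(abs(f$Resp_IE - 1), 0.05)
  expect_null(resp_features(rep(1, 1000), 128))   # no crossings: row drop
})

test_that("EDA features are simple sample statistics", {
  f <- eda_features(c(1, 2, 4))
  expect_equal(unname(unlist(f)), c(7 / 3, 4, 3))
  expect_equal(unname(unlist(eda_features(rep(5, 10)))), c(5, 5, 0))
  ramp <- seq(0.2, 0.8, length.out = 50)
  expect_equal(eda_features(ramp)$EDA_drange, 0.6)
  expect_null(eda_features(numeric(0)))
})

test_that("BVP peak frequency reads off the periodogram argmax", {
  t <- (0:(64 * 30 - 1)) / 64
  f <- bvp_features(sin(2 * pi * 1.2 * t), 64)
  expect_lt(abs(f$BVP_peak_freq - 1.2), 1 / 30 + 1e-9)

  prof <- subject_profile(baseline_hr = 90, sdnn = 0.02)
  b <- generate_bvp(prof, 60, 64, seed = 2)
  expect_lt(abs(bvp_features(b$series, 64)$BVP_peak_freq - 1.5), 0.1)

  expect_null(bvp_features(rep(2, 64 * 15), 64))  # DC only: row drop
  expect_null(bvp_features(sin(1:100), 64))       # window too short
})

test_that("accelerometer features split wrist and chest roles", {
  wrist <- list(x = c(-1, 0, 1), y = c(0, 0, 0), z = c(0, 0, 0))
  chest <- list(x = c(1, 2, 3), y = c(0, 0, 0), z = c(1, 1, 1))
  f <- acc_features(chest, wrist)
  expect_equal(f$ACC_x_mean, 0)
  expect_equal(f$ACC_x_min, -1)
  expect_equal(f$ACC_x_C_std, sqrt(2 / 3))        # population std of 1,2,3

  still <- list(x = rep(0, 5), y = rep(0, 5), z = rep(1, 5))
  f2 <- acc_features(still, still)
  expect_equal(f2$ACC_net_w_mean, 1)
  expect_equal(f2$ACC_net_w_std, 0)
  expect_null(acc_features(NULL, still))
})

test_that("walking windows are more dynamic than seated ones", {
  walk <- generate_acc("walking", 60, 32, seed = 5, device = "wrist")
  sit <- generate_acc("seated", 60, 32, seed = 5, device = "wrist")
  chest <- generate_acc("seated", 60, 64, seed = 5, device = "chest")
  f_walk <- acc_features(chest, walk)
  f_sit <- acc_features(chest, sit)
  expect_gt(f_walk$ACC_net_w_std, f_sit$ACC_net_w_std)
})

test_that("window extraction counts, labels and completes rows", {
  prof <- subject_profile()
  plan <- list(condition_interval(0, 300, "relaxation"))
  rec <- generate_session(prof, plan, seed = 4, label_noise = 0)
  ft <- extract_windows(rec, window_spec(60, 30))
  expect_equal(nrow(ft$rows), floor((300 - 60) / 30) + 1)  # 9 windows
  feats <- names(feature_modality_map())
  expect_true(all(feats %in% names(ft$rows)))
  expect_true(all(is.finite(as.matrix(ft$rows[, feats]))))
  expect_true(all(ft$rows$label == 0))
  expect_error(extract_windows(rec, window_spec(400, 30)), "longer")
})

test_that("a window straddling two conditions takes its midpoint label", {
  rec <- make_small_session(seed = 6, dur_each = 120)  # switch at 120 s
  ft <- extract_windows(rec, window_spec(60, 30))
  # the window at 90-150 s has midpoint 120 s, inside the second interval
  straddle <- ft$rows[ft$rows$window_start_s == 90, ]
  expect_equal(straddle$truth, 1L)
})

test_that("labels equal generator truth when label noise is off", {
  rec <- make_small_session(seed = 12, label_noise = 0)
  ft <- extract_windows(rec, window_spec(60, 30))
  expect_identical(ft$rows$label, ft$rows$truth)
})

test_that("anxiety shifts standardise into a large ECG_bpm effect size", {
  cfg <- cohort_config(12, "calibration", session_duration_s = 420,
                       seed = 17)
  ft <- cohort_features(generate_cohort(cfg, label_noise = 0),
                        spec = window_spec(60, 20), subset = "calibration")
  rows <- ft$rows
  expect_gte(nrow(rows), 200)
  calm <- rows$ECG_bpm[rows$truth == 0]
  anx <- rows$ECG_bpm[rows$truth == 1]
  pooled <- sqrt((stats::var(calm) + stats::var(anx)) / 2)
  smd <- (mean(anx) - mean(calm)) / pooled
  expect_gt(smd, 0.8)
})

test_that("feature tables round-trip through CSV + JSON", {
  rec <- make_small_session(seed = 7, dur_each = 90)
  ft <- extract_windows(rec, window_spec(60, 30), subset = "calibration")
  path <- tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(back$rows$ECG_bpm, ft$rows$ECG_bpm, tolerance = 1e-9)
  expect_equal(back$rows$label, ft$rows$label)
  unlink(c(path, paste0(path, ".json")))
})
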