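test_that("zero-phase Butterworth keeps DC, passband and kills stopband", {
  expect_equal(lowpass_butterworth(rep(3, 500), 128, 5), rep(3, 500),
               tolerance = 1e-9)

  t <- (0:(128 * 10 - 1)) / 128
  mid <- 257:1024
  hi <- sin(2 * pi * 20 * t)
  y_hi <- lowpass_butterworth(hi, 128, 5, order = 4)
  expect_lt(sqrt(mean(y_hi[mid]^2)) / sqrt(mean(hi[mid]^2)), 1e-2)

  lo <- sin(2 * pi * 0.5 * t)
  y_lo <- lowpass_butterworth(lo, 128, 5, order = 4)
  expect_lt(abs(sqrt(mean(y_lo[mid]^2)) / sqrt(mean(lo[mid]^2)) - 1), 0.01)

  expect_error(lowpass_butterworth(lo, 128, 70), "Nyquist")
})

test_that("zero-phase filtering leaves an in-band sinusoid unshifted", {
  t <- (0:1279) / 128
  x <- sin(2 * pi * 1 * t)
  y <- lowpass_butterworth(x, 128, 5, order = 4)
  cc <- stats::ccf(y, x, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("Hampel rule flags a lone spike but spares clean series", {
  r <- remove_outliers(c(1, 1, 1, 100, 1, 1, 1), window = 7, n_mad = 4)
  expect_identical(which(is.na(r$series)), 4L)
  expect_equal(r$report$n_outliers_replaced, 1L)

  ramp <- remove_outliers(seq(0, 10, length.out = 101), window = 7)
  expect_equal(ramp$report$n_outliers_replaced, 0L)

  const <- remove_outliers(rep(2, 50), window = 7)
  expect_equal(const$report$n_outliers_replaced, 0L)
})

test_that("min-max normalisation maps extremes to 0 and 1", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(-1, 0, 3)), c(0, 0.25, 1))
  x <- rnorm(100)
  y <- minmax_normalize(x)
  expect_equal(range(y), c(0, 1))
  x[4] <- NA
  expect_true(is.na(minmax_normalize(x)[4]))
  expect_error(minmax_normalize(rep(1, 5)), "degenerate")
})

test_that("downsampling honours the exact length contract and passband", {
  x <- sin(2 * pi * 3 * (0:699) / 700)
  expect_length(downsample(x, 700, 70), 70)

  t <- (0:(128 * 20 - 1)) / 128
  s <- sin(2 * pi * 1 * t)
  y <- downsample(s, 128, 32)
  mid <- 100:500
  expect_lt(abs(sqrt(mean(y[mid]^2)) * sqrt(2) - 1), 0.01)

  expect_identical(downsample(s, 128, 128), s)
  expect_error(downsample(s, 64, 128), "exceed")
})

test_that("mean imputation fills sparse gaps and drops heavy ones", {
  r <- impute_or_drop(c(1, NA, 3), max_missing_frac = 0.5)
  expect_equal(r$series, c(1, 2, 3))
  expect_equal(r$report$n_imputed, 1L)
  expect_false(r$report$dropped)

  x <- rnorm(100)
  x[1:30] <- NA
  r2 <- impute_or_drop(x, max_missing_frac = 0.2)
  expect_true(r2$report$dropped)

  clean <- rnorm(50)
  r3 <- impute_or_drop(clean)
  expect_identical(r3$series, clean)
  expect_equal(r3$report$n_imputed, 0L)

  # imputation preserves the observed mean exactly
  x4 <- c(rnorm(95), rep(NA, 5))
  r4 <- impute_or_drop(x4, 0.2)
  expect_equal(mean(r4$series), mean(x4, na.rm = TRUE))
})

test_that("noise injection calibrates to the requested linear SNR", {
  x <- rnorm(1e5)
  y <- add_gaussian_noise(x, 0.5, seed = 3)
  expect_lt(abs(var(y - x) / var(x) - 2), 0.1)  # noise var = var/SNR
  expect_identical(add_gaussian_noise(x, Inf), x)
  expect_error(add_gaussian_noise(x, -1), "positive")
  expect_error(add_gaussian_noise(rep(1, 10), 2), "non-constant")
  expect_identical(add_gaussian_noise(x, 0.5, seed = 3), y)
})

test_that("recording conditioning filters only EDA and ACC channels", {
  rec <- make_small_session(seed = 8, dur_each = 30)
  out <- preprocess_recording(rec)
  expect_false(identical(out$channels$ACC_C_x$samples,
                         rec$channels$ACC_C_x$samples))
  expect_identical(out$channels$ECG$samples, rec$channels$ECG$samples)
  # EDA at 4 Hz is already below twice the 5 Hz cutoff: left untouched
  expect_identical(out$channels$EDA$samples, rec$channels$EDA$samples)
})
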