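test_that("self-transfer reproduces resubstitution metrics exactly", {
  src <- make_feature_df(300, seed = 2)
  m <- train_source(src, model_spec("RF"), seed = 3)
  self <- evaluate_transfer(m, src)
  xy <- wearanx:::table_xy(src)
  resub <- classification_metrics(xy$y, predict(m, xy$X))
  expect_identical(self, resub)
})

test_that("evaluation is schema-safe under column permutation", {
  src <- make_feature_df(300, seed = 2)
  m <- train_source(src, model_spec("XGB"), seed = 3)
  base <- evaluate_transfer(m, src)
  perm <- src[, sample(ncol(src))]
  expect_identical(evaluate_transfer(m, perm), base)
  broken <- src
  broken$f1 <- NULL
  expect_error(evaluate_transfer(m, broken), "schema")
})

test_that("flipping target labels complements the accuracy", {
  src <- make_feature_df(300, seed = 4)
  m <- train_source(src, model_spec("DT"), seed = 1)
  base <- evaluate_transfer(m, src)
  flip <- src
  flip$label <- 1L - flip$label
  expect_equal(evaluate_transfer(m, flip)$accuracy, 1 - base$accuracy)
})

test_that("training is seed-deterministic and data-sensitive", {
  src <- make_feature_df(300, seed = 6)
  m1 <- train_source(src, model_spec("RF"), seed = 5)
  m2 <- train_source(src, model_spec("RF"), seed = 5)
  expect_identical(predict(m1, wearanx:::table_xy(src)$X),
                   predict(m2, wearanx:::table_xy(src)$X))
  shuffled <- src
  shuffled$f1 <- sample(shuffled$f1)
  m3 <- train_source(shuffled, model_spec("RF"), seed = 5)
  expect_false(identical(serialize(m1$fit, NULL), serialize(m3$fit, NULL)))
})

test_that("evaluation never mutates the frozen model", {
  src <- make_feature_df(200, seed = 8)
  tgt <- make_feature_df(200, seed = 9)
  m <- train_source(src, model_spec("SVM"), seed = 2)
  before <- serialize(m, NULL)
  invisible(evaluate_transfer(m, tgt))
  expect_identical(serialize(m, NULL), before)
})

test_that("same-distribution transfer tracks within-dataset CV", {
  diffs <- vapply(1:10, function(s) {
    src <- make_feature_df(300, shift = 4, seed = 200 + s)
    tgt <- make_feature_df(300, shift = 4, seed = 300 + s)
    cv <- crossval_evaluate(src, model_spec("LDA"), k = 5, iters = 1,
                            seed = s, compute_importance = FALSE)
    tr <- evaluate_transfer(train_source(src, model_spec("LDA"), seed = s),
                            tgt)
    abs(tr$f1 - cv$mean_f1)
  }, numeric(1))
  expect_lt(max(diffs), 0.1)
})

test_that("an effectively infinite SNR matches the no-noise baseline", {
  coh <- generate_cohort(cohort_config(2, "calibration",
                                       session_duration_s = 180, seed = 41),
                         label_noise = 0)
  tgt <- cohort_features(
    generate_cohort(cohort_config(2, "calibration",
                                  session_duration_s = 180, seed = 42),
                    label_noise = 0), subset = "calibration")
  spec <- model_spec("DT")
  res_hi <- snr_sweep(coh, grid = 1e6, specs = spec,
                      targets = list(calibration = tgt), seed = 7)
  res_inf <- snr_sweep(coh, grid = Inf, specs = spec,
                       targets = list(calibration = tgt), seed = 7)
  f1_hi <- res_hi$f1[res_hi$target == "calibration"]
  f1_inf <- res_inf$f1[res_inf$target == "calibration"]
  expect_lt(abs(f1_hi - f1_inf), 0.02)

  # result-grid shape: one record per (snr, model, target) plus the
  # within-source holdout rows
  res2 <- snr_sweep(coh, grid = c(0.01, 1e6),
                    specs = list(model_spec("DT"), model_spec("LDA")),
                    targets = list(calibration = tgt), seed = 7)
  expect_equal(nrow(res2), 2 * 2 * (1 + 1))
  expect_error(snr_sweep(coh, grid = numeric(0), specs = spec,
                         targets = list()), "empty")
})

test_that("report bundles round-trip and tolerate missing importance", {
  dir <- tempfile("report")
  res <- data.frame(source = "source", target = "calibration",
                    family = "DT", snr_linear = 0.1,
                    accuracy = 0.8, f1 = 0.75)
  s1 <- transfer_report(res, eval_results = NULL, importance = NULL,
                        dir = dir)
  expect_identical(s1$importance, "absent")
  back <- utils::read.csv(file.path(dir, "transfer_results.csv"))
  expect_equal(back$f1, res$f1)

  imp <- matrix(c(0.7, 0.3, 0.5, 0.5), 2, byrow = TRUE,
                dimnames = list(c("DT", "RF"), c("ECG_bpm", "EDA_mean")))
  s2 <- transfer_report(res, importance = imp, dir = dir)
  expect_equal(unname(s2$weight_entropy["RF"]), log(2), tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "feature_weights.csv")))
  unlink(dir, recursive = TRUE)
})
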