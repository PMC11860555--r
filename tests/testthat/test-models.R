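test_that("cross-validation separates separable data and is deterministic", {
  sep <- make_feature_df(300, seed = 2)
  e <- crossval_evaluate(sep, model_spec("LDA"), k = 5, iters = 2, seed = 4)
  expect_gte(e$mean_accuracy, 0.95)
  expect_equal(e$mean_accuracy, mean(e$per_fold$accuracy))
  expect_equal(e$mean_f1, mean(e$per_fold$f1))

  a <- crossval_evaluate(sep, model_spec("RF"), k = 5, iters = 2, seed = 7)
  b <- crossval_evaluate(sep, model_spec("RF"), k = 5, iters = 2, seed = 7)
  expect_identical(a, b)

  one_class <- sep
  one_class$label <- 0L
  expect_error(crossval_evaluate(one_class, model_spec("DT")),
               "both classes")
})

test_that("importances concentrate on the informative feature", {
  sep <- make_feature_df(300, shift = 5, seed = 3)
  for (fam in c("DT", "LDA", "XGB")) {
    e <- crossval_evaluate(sep, model_spec(fam), k = 5, iters = 1, seed = 1)
    expect_equal(names(which.max(e$importance)), "f1", label = fam)
    expect_equal(sum(e$importance), 1, tolerance = 1e-9)
  }
})

test_that("permutation importance of an uninformative feature is near zero", {
  df <- make_feature_df(300, p = 4, shift = 5, seed = 5)
  xy <- wearanx:::table_xy(df)
  m <- fit_model(model_spec("KNN"), xy$X, xy$y)
  imp <- permutation_importance(m, xy$X, xy$y, n_shuffles = 20, seed = 2)
  expect_lt(imp[["f3"]], 0.05)
  expect_gt(imp[["f1"]], 0.2)
})

test_that("duplicated feature columns share importance in boosted trees", {
  df <- make_feature_df(400, p = 3, shift = 4, seed = 6)
  xy <- wearanx:::table_xy(df)
  spec <- model_spec("XGB")
  base <- fit_model(spec, xy$X, xy$y)
  imp1 <- feature_importances(base, xy$X, xy$y)

  X2 <- cbind(xy$X, f1_copy = xy$X[, "f1"])
  dup <- fit_model(spec, X2, xy$y)
  imp2 <- feature_importances(dup, X2, xy$y)
  expect_lt(abs((imp2[["f1"]] + imp2[["f1_copy"]]) - imp1[["f1"]]), 0.05)
})

test_that("single-feature models get all the importance", {
  df <- data.frame(f1 = c(rnorm(50), rnorm(50) + 4),
                   label = rep(0:1, each = 50))
  xy <- wearanx:::table_xy(df)
  m <- fit_model(model_spec("DT"), xy$X, xy$y)
  expect_equal(unname(feature_importances(m, xy$X, xy$y)), 1)
})

test_that("squared-importance aggregation matches the closed form", {
  m <- rbind(c(0.6, 0.4), c(0.5, 0.5))
  colnames(m) <- c("f1", "f2")
  w <- aggregate_importance(m)
  expect_equal(unname(w), c(0.61, 0.41) / 1.02, tolerance = 1e-12)

  single <- matrix(c(1, 0), 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(aggregate_importance(single)), c(1, 0))

  unif <- matrix(1 / 5, 3, 5, dimnames = list(NULL, letters[1:5]))
  expect_equal(unname(aggregate_importance(unif)), rep(1 / 5, 5))

  expect_error(aggregate_importance(matrix(0, 2, 3)), "degenerate")
})

test_that("aggregation equals a brute-force double loop on random matrices", {
  brute <- function(m) {
    m <- sweep(m, 1, rowSums(m), "/")
    s <- numeric(ncol(m))
    for (f in seq_len(ncol(m))) {
      for (r in seq_len(nrow(m))) s[f] <- s[f] + m[r, f]^2
    }
    s / sum(s)
  }
  set.seed(11)
  for (rep in 1:20) {
    m <- matrix(runif(50), 5, 10,
                dimnames = list(NULL, paste0("f", 1:10)))
    w <- aggregate_importance(m)
    expect_equal(unname(w), brute(m), tolerance = 1e-12)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    # permutation invariance over features and models
    pf <- sample(10)
    pm <- sample(5)
    w_perm <- aggregate_importance(m[pm, pf])
    expect_equal(w_perm, w[pf], tolerance = 1e-12)
  }
})

test_that("a dominant feature wins the aggregated weight across seeds", {
  wins <- vapply(1:20, function(s) {
    df <- make_feature_df(200, p = 5, shift = 4, seed = 100 + s)
    xy <- wearanx:::table_xy(df)
    imp <- t(vapply(c("DT", "LDA", "XGB"), function(fam) {
      m <- fit_model(model_spec(fam, seed = s), xy$X, xy$y)
      feature_importances(m, xy$X, xy$y, seed = s)
    }, numeric(5)))
    names(which.max(aggregate_importance(imp))) == "f1"
  }, logical(1))
  expect_gte(sum(wins), 18)
})

test_that("modality rollup sums member features and ranks modalities", {
  w <- c(EDA_mean = 0.07, EDA_drange = 0.06, ECG_bpm = 0.5,
         TEMP_mean = 0.37)
  roll <- modality_rollup(w)
  expect_equal(unname(roll["EDA"]), 0.13)
  expect_equal(names(roll)[1], "ECG")
  expect_equal(unname(roll["ACC"]), 0)      # no member features -> 0
  expect_error(modality_rollup(c(bogus = 1)), "unmapped")

  all_one <- c(ECG_bpm = 1)
  expect_equal(unname(modality_rollup(all_one, map = c(ECG_bpm = "ECG"))), 1)
})

test_that("weight entropy measures dispersion", {
  expect_equal(importance_entropy(c(0.5, 0.5)), log(2))
  expect_equal(importance_entropy(c(1, 0)), 0)
  expect_lt(importance_entropy(c(0.9, 0.05, 0.05)),
            importance_entropy(rep(1 / 3, 3)))
})
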