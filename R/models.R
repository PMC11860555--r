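## The seven feature-based classifier families, the cross-validation
## protocol (k outer test folds, 80/20 inner train/validation split for
## hyperparameter choice, repeated iterations), per-model feature
## importances, and the squared-importance aggregation across models.

MODEL_FAMILIES <- c("DT", "RF", "LDA", "KNN", "AB", "SVM", "XGB")

#' Model specification
#'
#' @param family one of `"DT"` (decision tree), `"RF"` (random forest),
#'   `"LDA"`, `"KNN"`, `"AB"` (AdaBoost), `"SVM"` (RBF kernel), `"XGB"`.
#' @param hyperparameters optional list of hyperparameter settings to search
#'   on the inner validation split; defaults per family via
#'   [default_hyper_grid()].
#' @param seed integer seed used by stochastic fits.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family, hyperparameters = NULL, seed = 1) {
  family <- match.arg(family, MODEL_FAMILIES)
  grid <- hyperparameters %||% default_hyper_grid(family)
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "model_spec")
}

#' Default hyperparameter grids
#'
#' Small fixed grids searched on the inner 80/20 validation split; the first
#' entry of each grid is the family's default setting.
#'
#' @param family model family code.
#' @return List of hyperparameter lists.
#' @export
default_hyper_grid <- function(family) {
  switch(family,
         DT = list(list(maxdepth = 8), list(maxdepth = 4)),
         RF = list(list(ntree = 200)),
         LDA = list(list()),
         KNN = list(list(k = 5), list(k = 11)),
         AB = list(list(n_rounds = 30, maxdepth = 2)),
         SVM = list(list(cost = 1), list(cost = 10)),
         XGB = list(list(nrounds = 50, max_depth = 4, eta = 0.3)),
         stop("unknown model family: ", family, call. = FALSE))
}

## feature-column extraction: canonical names for feature tables, all
## non-bookkeeping numeric columns otherwise
table_xy <- function(table) {
  rows <- if (inherits(table, "feature_table")) table$rows else table
  book <- c("subject_id", "window_start_s", "label", "truth", "subset")
  feats <- setdiff(names(rows), book)
  X <- as.matrix(rows[, feats, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = as.integer(rows$label))
}

make_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

#' Fit one classifier family
#'
#' @param spec a [model_spec()].
#' @param X numeric feature matrix (named columns).
#' @param y integer 0/1 labels (1 = anxious).
#' @param hyper hyperparameter list; default is the first grid entry.
#' @return An object of class `wearanx_model` carrying the fitted model, the
#'   feature schema (names and order), and any input scaler.
#' @export
fit_model <- function(spec, X, y, hyper = NULL) {
  hyper <- hyper %||% spec$grid[[1]]
  family <- spec$family
  schema <- colnames(X)
  yf <- factor(y, levels = c(0, 1))
  scaler <- NULL
  seed <- derive_seed(spec$seed, family)
  fit <- switch(
    family,
    DT = {
      df <- data.frame(X, check.names = FALSE)
      df$.y <- yf
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = hyper$maxdepth %||% 8, cp = 0.001,
                     xval = 0))
    },
    RF = local_seed(seed, {
      randomForest::randomForest(x = X, y = yf,
                                 ntree = hyper$ntree %||% 200)
    }),
    LDA = {
      scaler <- make_scaler(X)
      MASS::lda(apply_scaler(X, scaler), grouping = yf)
    },
    KNN = {
      scaler <- make_scaler(X)
      list(train = apply_scaler(X, scaler), y = yf, k = hyper$k %||% 5)
    },
    AB = adaboost_fit(X, y, n_rounds = hyper$n_rounds %||% 30,
                      maxdepth = hyper$maxdepth %||% 2, seed = seed),
    SVM = {
      scaler <- make_scaler(X)
      local_seed(seed, {
        e1071::svm(apply_scaler(X, scaler), yf,
                   kernel = hyper$kernel %||% "radial",
                   cost = hyper$cost %||% 1)
      })
    },
    XGB = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hyper$max_depth %||% 4,
                      eta = hyper$eta %||% 0.3,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = hyper$nrounds %||% 50, verbose = 0)
    })
  structure(list(family = family, fit = fit, schema = schema,
                 scaler = scaler, hyper = hyper, seed = seed),
            class = "wearanx_model")
}

#' Predict anxiety labels from a fitted model
#'
#' Feature columns are aligned to the training schema by name, so column
#' order in `newdata` is irrelevant; a missing feature is a schema error.
#'
#' @param object a `wearanx_model`.
#' @param newdata numeric feature matrix or data frame.
#' @param ... unused.
#' @return Integer vector of 0/1 predictions.
#' @export
predict.wearanx_model <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) {
    as.matrix(newdata[, intersect(object$schema, names(newdata)),
                      drop = FALSE])
  } else newdata
  miss <- setdiff(object$schema, colnames(X))
  if (length(miss) > 0) {
    stop("schema error: missing features ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- X[, object$schema, drop = FALSE]
  storage.mode(X) <- "double"
  family <- object$family
  fit <- object$fit
  out <- switch(
    family,
    DT = {
      df <- data.frame(X, check.names = FALSE)
      as.integer(as.character(predict(fit, df, type = "class")))
    },
    RF = as.integer(as.character(predict(fit, X))),
    LDA = as.integer(as.character(
      predict(fit, apply_scaler(X, object$scaler))$class)),
    KNN = local_seed(object$seed, {
      as.integer(as.character(
        class::knn(fit$train, apply_scaler(X, object$scaler), fit$y,
                   k = fit$k)))
    }),
    AB = predict_adaboost(fit, X),
    SVM = as.integer(as.character(
      predict(fit, apply_scaler(X, object$scaler)))),
    XGB = as.integer(
      predict(fit, xgboost::xgb.DMatrix(X, nthread = 1)) >= 0.5))
  out
}

#' Binary classification metrics
#'
#' @param y true 0/1 labels.
#' @param pred predicted 0/1 labels.
#' @return List with `accuracy` and `f1` (positive class = anxious = 1; 0 by
#'   convention when precision and recall are both undefined).
#' @export
classification_metrics <- function(y, pred) {
  tp <- sum(y == 1 & pred == 1)
  fp <- sum(y == 0 & pred == 1)
  fn <- sum(y == 1 & pred == 0)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(accuracy = mean(y == pred), f1 = f1)
}

## stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  local_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated model evaluation
#'
#' The table is split into `k` stratified test folds. For each fold, the
#' remaining rows are split 80/20 (stratified) into a training and a
#' validation part; every hyperparameter setting in the spec's grid is fit
#' on the training part and scored on the validation part, the best setting
#' is retained, and its model is scored on the held-out test fold. The whole
#' procedure is repeated `iters` times with distinct fold seeds and the
#' metrics averaged.
#'
#' @param table a `feature_table` or data frame with a `label` column.
#' @param spec a [model_spec()].
#' @param k number of outer folds (default 5).
#' @param iters number of repetitions (default 5).
#' @param seed integer seed; the same table, spec and seed give an identical
#'   result.
#' @param compute_importance also fit on the full table and attach the
#'   normalised feature-importance vector (default `TRUE`).
#' @return An object of class `eval_result` with `per_fold` metrics, their
#'   means, and the importance vector.
#' @export
crossval_evaluate <- function(table, spec, k = 5, iters = 5, seed = 1,
                              compute_importance = TRUE) {
  xy <- table_xy(table)
  X <- xy$X
  y <- xy$y
  if (length(unique(y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  if (min(table(y)) < k) {
    stop("stratification error: minority class smaller than fold count",
         call. = FALSE)
  }
  per_fold <- vector("list", k * iters)
  row_i <- 0L
  for (it in seq_len(iters)) {
    it_seed <- derive_seed(seed, spec$family, it)
    folds <- stratified_folds(y, k, it_seed)
    for (f in seq_len(k)) {
      test_idx <- which(folds == f)
      rest_idx <- which(folds != f)
      inner <- stratified_folds(y[rest_idx], 5, derive_seed(it_seed, f))
      val_idx <- rest_idx[inner == 1]       # 20% validation
      train_idx <- rest_idx[inner != 1]     # 80% training
      best <- spec$grid[[1]]
      if (length(spec$grid) > 1) {
        best_acc <- -Inf
        for (h in spec$grid) {
          m_h <- fit_model(spec, X[train_idx, , drop = FALSE], y[train_idx],
                           hyper = h)
          acc <- mean(predict(m_h, X[val_idx, , drop = FALSE]) == y[val_idx])
          if (acc > best_acc) {
            best_acc <- acc
            best <- h
          }
        }
      }
      m <- fit_model(spec, X[train_idx, , drop = FALSE], y[train_idx],
                     hyper = best)
      met <- classification_metrics(y[test_idx],
                                    predict(m, X[test_idx, , drop = FALSE]))
      row_i <- row_i + 1L
      per_fold[[row_i]] <- data.frame(iter = it, fold = f,
                                      accuracy = met$accuracy, f1 = met$f1)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  importance <- NULL
  if (compute_importance) {
    full <- fit_model(spec, X, y)
    importance <- feature_importances(full, X, y,
                                      seed = derive_seed(seed, "imp"))
  }
  structure(list(family = spec$family, per_fold = per_fold,
                 mean_accuracy = mean(per_fold$accuracy),
                 mean_f1 = mean(per_fold$f1),
                 importance = importance),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s: accuracy %.3f, F1 %.3f over %d folds\n",
              x$family, x$mean_accuracy, x$mean_f1, nrow(x$per_fold)))
  invisible(x)
}

#' Permutation feature importance
#'
#' Mean drop in accuracy over `n_shuffles` seeded permutations of each
#' feature column, clipped at zero.
#'
#' @param model a fitted `wearanx_model`.
#' @param X,y evaluation features and labels.
#' @param n_shuffles permutations per feature (default 20).
#' @param seed integer seed.
#' @return Non-negative importance vector (not yet normalised).
#' @export
permutation_importance <- function(model, X, y, n_shuffles = 20, seed = 1) {
  base_acc <- mean(predict(model, X) == y)
  imp <- stats::setNames(numeric(ncol(X)), colnames(X))
  local_seed(seed, {
    for (j in seq_len(ncol(X))) {
      drop_j <- numeric(n_shuffles)
      for (s in seq_len(n_shuffles)) {
        Xp <- X
        Xp[, j] <- X[sample(nrow(X)), j]
        drop_j[s] <- base_acc - mean(predict(model, Xp) == y)
      }
      imp[j] <- max(0, mean(drop_j))
    }
  })
  imp
}

#' Per-model feature importances
#'
#' Tree families (DT, RF, AB, XGB) report impurity-based importances; LDA
#' and linear-kernel SVM report absolute standardised discriminant/ weight
#' coefficients; KNN and nonlinear SVM fall back to seeded permutation
#' importance. The vector is normalised to sum 1 (uniform if degenerate).
#'
#' @param model a fitted `wearanx_model`.
#' @param X,y the table the model was fitted on (used by permutation
#'   importance).
#' @param n_shuffles permutation count for permutation-based families.
#' @param seed integer seed.
#' @return Named importance vector over the model's schema, summing to 1.
#' @export
feature_importances <- function(model, X, y, n_shuffles = 20, seed = 1) {
  if (!inherits(model, "wearanx_model")) {
    stop("`model` must be a fitted wearanx_model", call. = FALSE)
  }
  schema <- model$schema
  raw <- stats::setNames(numeric(length(schema)), schema)
  fam <- model$family
  if (fam == "DT") {
    vi <- model$fit$variable.importance
    if (!is.null(vi)) raw[names(vi)] <- vi
  } else if (fam == "RF") {
    vi <- randomForest::importance(model$fit)[, "MeanDecreaseGini"]
    raw[names(vi)] <- vi
  } else if (fam == "AB") {
    vi <- adaboost_importance(model$fit)
    raw[names(vi)] <- vi
  } else if (fam == "XGB") {
    vi <- xgboost::xgb.importance(model = model$fit)
    raw[vi$Feature] <- vi$Gain
  } else if (fam == "LDA") {
    ## inputs were standardised at fit time, so |scaling| is standardised
    raw[] <- abs(model$fit$scaling[schema, 1])
  } else if (fam == "SVM" && identical(model$hyper$kernel, "linear")) {
    w <- t(model$fit$coefs) %*% model$fit$SV
    raw[colnames(w)] <- abs(as.numeric(w))
  } else {
    raw <- permutation_importance(model, X, y, n_shuffles = n_shuffles,
                                  seed = seed)
  }
  raw[!is.finite(raw) | raw < 0] <- 0
  if (sum(raw) == 0) {
    rep(1 / length(raw), length(raw))
  } else {
    raw / sum(raw)
  }
}

#' Aggregate feature importances across models (squared-importance weights)
#'
#' Each model's importance row is normalised to sum 1; a feature's score is
#' the sum of its squared importances across models, and the weights are
#' those scores divided by their total, so they again sum to 1. Squaring
#' emphasises features that are consistently influential across models.
#'
#' @param m non-negative model-by-feature importance matrix (models in rows,
#'   named feature columns).
#' @param denominator `"squared"` (default; the total of the squared-summed
#'   scores, giving a proper distribution) or `"raw"` (the total of the raw
#'   importances).
#' @return Named weight vector over features.
#' @export
aggregate_importance <- function(m, denominator = c("squared", "raw")) {
  denominator <- match.arg(denominator)
  m <- as.matrix(m)
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("importances must be finite and non-negative", call. = FALSE)
  }
  rs <- rowSums(m)
  if (all(rs == 0)) stop("degenerate input: all importances zero",
                         call. = FALSE)
  m <- m[rs > 0, , drop = FALSE]
  m <- sweep(m, 1, rowSums(m), "/")
  s <- colSums(m^2)
  denom <- if (denominator == "squared") sum(s) else sum(m)
  s / denom
}

#' Roll feature weights up to modalities
#'
#' @param weights named feature-weight vector (e.g. from
#'   [aggregate_importance()]).
#' @param map named feature-to-modality character vector; every weighted
#'   feature must be mapped.
#' @param modalities optional modality universe; modalities with no member
#'   features report weight 0.
#' @return Named modality-weight vector, sorted decreasing.
#' @export
modality_rollup <- function(weights, map = feature_modality_map(),
                            modalities = NULL) {
  unmapped <- setdiff(names(weights), names(map))
  if (length(unmapped) > 0) {
    stop("unmapped features: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  mods <- modalities %||% unique(unname(map))
  out <- stats::setNames(rep(0, length(mods)), mods)
  agg <- tapply(weights, map[names(weights)], sum)
  out[names(agg)] <- agg
  sort(out, decreasing = TRUE)
}

#' Shannon entropy of a weight vector
#'
#' Reported alongside transfer scores as a dispersion statistic: higher
#' entropy means importance is spread more evenly across features.
#'
#' @param weights non-negative weights (renormalised internally).
#' @return Entropy in nats.
#' @export
importance_entropy <- function(weights) {
  w <- weights[weights > 0]
  w <- w / sum(w)
  -sum(w * log(w))
}
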