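## Discrete AdaBoost (SAMME with two classes) over shallow rpart trees.
## Weak learners are depth-limited classification trees fit with case
## weights; the ensemble prediction is the alpha-weighted vote.

adaboost_fit <- function(X, y, n_rounds = 30, maxdepth = 2, seed = 1) {
  yy <- ifelse(y == 1, 1, -1)
  n <- length(yy)
  df <- data.frame(X, check.names = FALSE)
  df$.y <- factor(yy, levels = c(-1, 1))
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = 0, minsplit = 5,
                               xval = 0)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  local_seed(seed, {
    for (m in seq_len(n_rounds)) {
      fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = ctrl)
      pred <- as.numeric(as.character(predict(fit, df, type = "class")))
      err <- sum(w[pred != yy])
      if (err <= 1e-12) {          # perfect weak learner: dominate the vote
        stumps[[length(stumps) + 1]] <- fit
        alphas <- c(alphas, 10)
        break
      }
      if (err >= 0.5) break        # no better than chance under these weights
      alpha <- 0.5 * log((1 - err) / err)
      stumps[[length(stumps) + 1]] <- fit
      alphas <- c(alphas, alpha)
      w <- w * exp(-alpha * yy * pred)
      w <- w / sum(w)
    }
  })
  if (length(stumps) == 0) {
    ## degenerate: fall back to the majority class
    maj <- if (mean(yy) >= 0) 1 else -1
    return(structure(list(stumps = list(), alphas = numeric(0),
                          majority = maj, features = colnames(X)),
                     class = "adaboost"))
  }
  structure(list(stumps = stumps, alphas = alphas, majority = NULL,
                 features = colnames(X)),
            class = "adaboost")
}

predict_adaboost <- function(object, X) {
  if (length(object$stumps) == 0) {
    return(rep(if (object$majority == 1) 1L else 0L, nrow(X)))
  }
  df <- data.frame(X, check.names = FALSE)
  score <- rep(0, nrow(df))
  for (m in seq_along(object$stumps)) {
    pred <- as.numeric(as.character(
      predict(object$stumps[[m]], df, type = "class")))
    score <- score + object$alphas[m] * pred
  }
  as.integer(score >= 0)
}

adaboost_importance <- function(object) {
  imp <- stats::setNames(rep(0, length(object$features)), object$features)
  for (m in seq_along(object$stumps)) {
    vi <- object$stumps[[m]]$variable.importance
    if (!is.null(vi)) {
      imp[names(vi)] <- imp[names(vi)] + object$alphas[m] * vi
    }
  }
  imp
}
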