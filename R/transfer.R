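## Transfer-learning harness: train on a (optionally noise-augmented)
## source dataset, evaluate on target feature tables with no fine-tuning,
## sweep the SNR grid, and bundle results for reporting.

#' Default SNR grid for noise augmentation
#'
#' Linear signal-to-noise power ratios spanning the augmentation range
#' 0.0001-0.6 on a roughly logarithmic grid.
#'
#' @return Sorted numeric vector.
#' @export
snr_grid <- function() c(0.0001, 0.001, 0.01, 0.1, 0.3, 0.6)

#' Train a source model for transfer evaluation
#'
#' Fits the family on the full source table (default hyperparameters, no
#' target exposure); the fitted model carries its feature schema and is
#' never refit at evaluation time.
#'
#' @param source_table a `feature_table` or data frame with `label`.
#' @param spec a [model_spec()].
#' @param seed integer seed.
#' @return A fitted `wearanx_model`.
#' @export
train_source <- function(source_table, spec, seed = 1) {
  xy <- table_xy(source_table)
  spec$seed <- as.integer(seed)
  fit_model(spec, xy$X, xy$y)
}

#' Evaluate a trained model on a target table without fine-tuning
#'
#' Predicts every target row through the frozen model (columns aligned to
#' the source schema by name) and returns accuracy and anxious-class F1.
#'
#' @param fitted a `wearanx_model` from [train_source()].
#' @param target_table a `feature_table` or data frame with `label`.
#' @return List with `accuracy` and `f1`.
#' @export
evaluate_transfer <- function(fitted, target_table) {
  xy <- table_xy(target_table)
  classification_metrics(xy$y, predict(fitted, xy$X))
}

#' Noise-augmentation transfer sweep
#'
#' For every SNR in the grid, Gaussian noise at that linear SNR is injected
#' into the raw source recordings, features are re-extracted, each model
#' family is trained on the noisy source table, and the frozen model is
#' evaluated on every target table (plus a held-out within-source split).
#' `Inf` in the grid means no augmentation.
#'
#' @param source_recordings list of `multimodal_recording`s (raw source).
#' @param grid numeric vector of linear SNRs (see [snr_grid()]); may include
#'   `Inf` for the no-noise baseline.
#' @param specs list of [model_spec()]s.
#' @param targets named list of target `feature_table`s.
#' @param window a [window_spec()] for feature extraction.
#' @param label a [label_spec()].
#' @param seed integer seed.
#' @param holdout_frac fraction of source rows held out for the
#'   within-source evaluation (default 0.25).
#' @return Data frame of class `transfer_result` with one row per
#'   (snr, model, target): columns `source`, `target`, `family`,
#'   `snr_linear`, `accuracy`, `f1`.
#' @export
snr_sweep <- function(source_recordings, grid = snr_grid(), specs,
                      targets, window = window_spec(), label = label_spec(),
                      seed = 1, holdout_frac = 0.25) {
  if (length(grid) == 0) stop("empty SNR grid", call. = FALSE)
  if (any(grid <= 0)) stop("SNRs must be positive", call. = FALSE)
  if (inherits(specs, "model_spec")) specs <- list(specs)
  results <- list()
  for (snr in grid) {
    noisy <- lapply(seq_along(source_recordings), function(i) {
      if (is.infinite(snr)) source_recordings[[i]]
      else noise_augment_recording(source_recordings[[i]], snr,
                                   seed = derive_seed(seed, i, round(1e6 * min(snr, 1000))))
    })
    src_tab <- cohort_features(noisy, spec = window, label = label,
                               subset = "source")
    xy <- table_xy(src_tab)
    ## stratified within-source holdout, fixed across SNRs
    folds <- stratified_folds(xy$y, max(2L, round(1 / holdout_frac)),
                              derive_seed(seed, "holdout"))
    hold <- folds == 1
    for (spec in specs) {
      train_rows <- src_tab$rows[!hold, , drop = FALSE]
      m <- train_source(train_rows, spec, seed = derive_seed(seed, spec$family))
      met_src <- classification_metrics(
        xy$y[hold], predict(m, xy$X[hold, , drop = FALSE]))
      results[[length(results) + 1]] <- data.frame(
        source = "source", target = "source_holdout", family = spec$family,
        snr_linear = snr, accuracy = met_src$accuracy, f1 = met_src$f1)
      for (tg in names(targets)) {
        met <- evaluate_transfer(m, targets[[tg]])
        results[[length(results) + 1]] <- data.frame(
          source = "source", target = tg, family = spec$family,
          snr_linear = snr, accuracy = met$accuracy, f1 = met$f1)
      }
    }
  }
  out <- do.call(rbind, results)
  class(out) <- c("transfer_result", class(out))
  out
}

#' Write a transfer/evaluation report bundle
#'
#' Writes the transfer grid, per-model CV metrics, the importance matrix
#' with its aggregated weights, modality rollup, and per-model weight
#' entropy to CSV/JSON under `dir`.
#'
#' @param results `transfer_result` data frame from [snr_sweep()] (or
#'   `NULL`).
#' @param eval_results named list of `eval_result`s (or `NULL`).
#' @param importance model-by-feature importance matrix (or `NULL`; the
#'   report notes its absence).
#' @param dir output directory.
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
transfer_report <- function(results = NULL, eval_results = NULL,
                            importance = NULL, dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list()
  if (!is.null(results) && nrow(results) > 0) {
    utils::write.csv(results, file.path(dir, "transfer_results.csv"),
                     row.names = FALSE)
    summary$n_transfer_records <- nrow(results)
  }
  if (!is.null(eval_results)) {
    cv <- do.call(rbind, lapply(eval_results, function(e) {
      data.frame(family = e$family, accuracy = e$mean_accuracy,
                 f1 = e$mean_f1)
    }))
    utils::write.csv(cv, file.path(dir, "cv_metrics.csv"), row.names = FALSE)
    summary$cv <- cv
  }
  if (is.null(importance) || length(importance) == 0) {
    summary$importance <- "absent"
  } else {
    utils::write.csv(as.data.frame(importance),
                     file.path(dir, "importance_matrix.csv"))
    weights <- aggregate_importance(importance)
    utils::write.csv(
      data.frame(feature = names(weights), weight = unname(weights)),
      file.path(dir, "feature_weights.csv"), row.names = FALSE)
    known <- intersect(names(weights), names(feature_modality_map()))
    if (length(known) == length(weights)) {
      roll <- modality_rollup(weights)
      utils::write.csv(
        data.frame(modality = names(roll), weight = unname(roll)),
        file.path(dir, "modality_weights.csv"), row.names = FALSE)
      summary$modality_weights <- as.list(roll)
    }
    summary$weight_entropy <- apply(
      sweep(as.matrix(importance), 1, rowSums(as.matrix(importance)), "/"),
      1, importance_entropy)
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(summary)
}

#' Plot transfer F1 against SNR
#'
#' @param results `transfer_result` data frame.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_transfer <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  snr_linear <- f1 <- family <- NULL  # quiet non-standard-eval lints
  ggplot2::ggplot(results,
                  ggplot2::aes(x = snr_linear, y = f1, colour = family)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~target) +
    ggplot2::labs(x = "training SNR (linear)", y = "F1 (anxious class)",
                  colour = "model")
}
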