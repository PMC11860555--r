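#' Write a multimodal recording to disk
#'
#' One CSV per channel (columns `t_s`, `value`) plus a JSON sidecar holding
#' the channel map (sampling rate and device per channel), annotations,
#' ground-truth beat times and the generator seed.
#'
#' @param recording a `multimodal_recording`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir) {
  if (!inherits(recording, "multimodal_recording")) {
    stop("`recording` must be a multimodal_recording", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(recording$channels)) {
    ch <- recording$channels[[nm]]
    df <- data.frame(t_s = sample_times(length(ch$samples), ch$fs),
                     value = ch$samples)
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  meta <- list(
    subject_id = recording$subject_id,
    seed = recording$seed,
    channels = lapply(recording$channels, function(ch) {
      list(fs = ch$fs, device = ch$device, n = length(ch$samples))
    }),
    annotations = lapply(recording$annotations, function(a) {
      list(start_s = a$start_s, end_s = a$end_s, condition = a$condition,
           stai_y6 = a$stai_y6, anxious_truth = a$anxious_truth)
    }),
    true_beats_s = recording$true_beats_s)
  jsonlite::write_json(meta, file.path(dir, "recording.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a multimodal recording written by [write_recording()]
#'
#' @param dir directory containing per-channel CSVs and `recording.json`.
#' @return A `multimodal_recording`.
#' @export
read_recording <- function(dir) {
  meta_path <- file.path(dir, "recording.json")
  if (!file.exists(meta_path)) {
    stop("no recording.json found in ", dir, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  channels <- lapply(names(meta$channels), function(nm) {
    df <- utils::read.csv(file.path(dir, paste0(nm, ".csv")))
    list(samples = df$value, fs = meta$channels[[nm]]$fs,
         device = meta$channels[[nm]]$device)
  })
  names(channels) <- names(meta$channels)
  annotations <- lapply(meta$annotations, function(a) {
    condition_interval(a$start_s, a$end_s, a$condition,
                       stai_y6 = a$stai_y6, anxious_truth = a$anxious_truth)
  })
  structure(list(channels = channels, annotations = annotations,
                 true_beats_s = unlist(meta$true_beats_s),
                 subject_id = meta$subject_id,
                 seed = meta$seed),
            class = "multimodal_recording")
}

#' Write / read a feature table
#'
#' The feature table travels as CSV (one row per window, canonical feature
#' names in the header) plus a JSON sidecar with the window spec, drop
#' counts and the feature-to-modality map.
#'
#' @param table a `feature_table` (see [extract_windows()]).
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table$rows, path, row.names = FALSE)
  jsonlite::write_json(
    list(window = unclass(table$window), drop_counts = table$drop_counts,
         feature_to_modality = as.list(table$feature_to_modality)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(rows = rows,
                 window = window_spec(meta$window$length_s,
                                      meta$window$shift_s),
                 drop_counts = meta$drop_counts,
                 feature_to_modality = unlist(meta$feature_to_modality)),
            class = "feature_table")
}
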