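## STAI-based labelling, subset assembly and majority-class undersampling.

#' STAI Y6 labelling specification
#'
#' The 6-item short-form state-anxiety score ranges over 6..24; scores at or
#' above the cutoff (default 11) are labelled anxious. The boundary score
#' counts as anxious by default; set `strict = TRUE` for a strict-greater
#' rule.
#'
#' @param cutoff anxiety threshold on the STAI Y6 (default 11).
#' @param strict label anxious only strictly above the cutoff.
#' @return An object of class `label_spec`.
#' @export
label_spec <- function(cutoff = 11, strict = FALSE) {
  if (cutoff < 6 || cutoff > 24) {
    stop("`cutoff` must lie within the STAI Y6 range [6, 24]", call. = FALSE)
  }
  structure(list(cutoff = cutoff, range = c(6, 24), strict = isTRUE(strict)),
            class = "label_spec")
}

#' Dichotomise a STAI Y6 score
#'
#' @param score integer score(s) in 6..24.
#' @param spec a [label_spec()].
#' @return 1 (anxious) when `score >= cutoff` (or `>` under `strict`),
#'   else 0.
#' @export
label_from_stai <- function(score, spec = label_spec()) {
  if (any(!is.finite(score)) || any(score < 6) || any(score > 24)) {
    stop("STAI Y6 scores must lie in [6, 24]", call. = FALSE)
  }
  as.integer(if (spec$strict) score > spec$cutoff else score >= spec$cutoff)
}

#' Undersample the majority class to a target minority fraction
#'
#' Keeps every minority-class row and a uniform random subset of
#' `round(n_min * (1 - p) / p)` majority rows for target minority fraction
#' `p`. A table already at (or within one row of) the target is returned
#' unchanged; a target below the current minority fraction is an error
#' (undersampling can only raise it).
#'
#' @param table a `feature_table` (or plain data frame with a `label`
#'   column).
#' @param target_minority_frac target minority fraction in (0, 1).
#' @param seed integer seed for the majority subsample.
#' @return A list: `table` (rebalanced) and `report`, a `balance_report`
#'   with before/after class counts and the number of removed rows.
#' @export
undersample <- function(table, target_minority_frac, seed = 1) {
  if (target_minority_frac <= 0 || target_minority_frac >= 1) {
    stop("`target_minority_frac` must lie in (0, 1)", call. = FALSE)
  }
  is_ft <- inherits(table, "feature_table")
  rows <- if (is_ft) table$rows else table
  counts <- table(factor(rows$label, levels = c(0, 1)))
  if (any(counts == 0)) {
    stop("both classes must be present to rebalance", call. = FALSE)
  }
  minority <- names(counts)[which.min(counts)]
  n_min <- min(counts)
  n_maj <- max(counts)
  current <- n_min / (n_min + n_maj)
  keep_maj <- round(n_min * (1 - target_minority_frac) / target_minority_frac)
  if (keep_maj >= n_maj) {
    if (keep_maj > n_maj + 1) {
      stop("target minority fraction is below the current fraction; ",
           "undersampling cannot lower it", call. = FALSE)
    }
    report <- balance_report(before = as.integer(counts),
                             after = as.integer(counts),
                             target = target_minority_frac, n_removed = 0L)
    return(list(table = table, report = report))
  }
  idx_min <- which(rows$label == as.integer(minority))
  idx_maj <- which(rows$label != as.integer(minority))
  sel_maj <- local_seed(seed, sort(sample(idx_maj, keep_maj)))
  sel <- sort(c(idx_min, sel_maj))
  new_rows <- rows[sel, , drop = FALSE]
  rownames(new_rows) <- NULL
  after <- table(factor(new_rows$label, levels = c(0, 1)))
  report <- balance_report(before = as.integer(counts),
                           after = as.integer(after),
                           target = target_minority_frac,
                           n_removed = n_maj - keep_maj)
  out <- if (is_ft) {
    table$rows <- new_rows
    table
  } else new_rows
  list(table = out, report = report)
}

#' Balance report
#'
#' @param before,after class counts (calm, anxious) before and after
#'   undersampling.
#' @param target target minority fraction.
#' @param n_removed majority rows removed.
#' @return An object of class `balance_report`.
#' @export
balance_report <- function(before, after, target, n_removed) {
  structure(list(before = before, after = after,
                 target_minority_frac = target,
                 n_removed = as.integer(n_removed)),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> (%d, %d) -> (%d, %d), removed %d, target %.2f\n",
              x$before[1], x$before[2], x$after[1], x$after[2],
              x$n_removed, x$target_minority_frac))
  invisible(x)
}

#' Assemble the three analysis subsets
#'
#' Calibration and in-lab tables (already near balance by protocol design)
#' pass through unchanged; the in-the-wild table is returned raw and at the
#' two rebalanced minority fractions, 30% and 41%.
#'
#' @param cohort_tables named list of `feature_table`s with names among
#'   `calibration`, `in_lab`, `in_the_wild`.
#' @param seed seed for the undersampling draws.
#' @return Named list of tables; the in-the-wild entries are
#'   `in_the_wild_raw`, `in_the_wild_30`, `in_the_wild_41`.
#' @export
assemble_subsets <- function(cohort_tables, seed = 1) {
  if (is.null(names(cohort_tables)) ||
      !all(names(cohort_tables) %in% c("calibration", "in_lab", "in_the_wild"))) {
    stop("tables must be named calibration / in_lab / in_the_wild",
         call. = FALSE)
  }
  n_rows <- function(t) nrow(if (inherits(t, "feature_table")) t$rows else t)
  if (any(vapply(cohort_tables, n_rows, integer(1)) == 0)) {
    stop("empty subset table", call. = FALSE)
  }
  out <- list()
  if (!is.null(cohort_tables$calibration)) {
    out$calibration <- cohort_tables$calibration
  }
  if (!is.null(cohort_tables$in_lab)) out$in_lab <- cohort_tables$in_lab
  if (!is.null(cohort_tables$in_the_wild)) {
    wild <- cohort_tables$in_the_wild
    out$in_the_wild_raw <- wild
    out$in_the_wild_30 <- undersample(wild, 0.30,
                                      seed = derive_seed(seed, 30))$table
    out$in_the_wild_41 <- undersample(wild, 0.41,
                                      seed = derive_seed(seed, 41))$table
  }
  out
}
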