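#' Mean DTW distance of a condition's steps to the reference
#'
#' Each recorded condition (e.g. before or after surgery) contributes
#' several steps; its distance to the healthy reference is the aggregate of
#' the per-step DTW distances. Steps of unequal length are compared
#' directly — DTW needs no resampling.
#'
#' @param reference_step Amplitude-normalized reference stance curve.
#' @param steps List of amplitude-normalized step sequences.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return The aggregated DTW distance, a non-negative scalar.
#' @export
condition_distance <- function(reference_step, steps,
                               aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (!is.list(steps)) steps <- list(steps)
  if (length(steps) == 0L) stop("at least one step is required", call. = FALSE)
  d <- vapply(steps, function(s) dtw_distance(reference_step, s), numeric(1))
  if (aggregate == "mean") mean(d) else stats::median(d)
}

#' Improvement percentage from a normalized error
#'
#' With each subject's distances normalized so the pre-treatment error is
#' exactly 1, the outcome statistic is
#' `improvement = round(100 * (1 - error_after))` percent. An error above 1
#' (the subject worsened) gives a negative improvement.
#'
#' @param error_after Normalized post-treatment error, `>= 0` (vectorized).
#' @return Integer percentage(s).
#' @examples
#' improvement(0.06)  # 94
#' improvement(0.11)  # 89
#' @export
improvement <- function(error_after) {
  if (any(!is.finite(error_after)) || any(error_after < 0)) {
    stop("error_after must be finite and >= 0", call. = FALSE)
  }
  as.integer(round(100 * (1 - error_after)))
}

#' Build a per-subject improvement report
#'
#' @param subject_id Identifier.
#' @param raw_distance_before,raw_distance_after Raw per-condition DTW
#'   distances to the reference; `raw_distance_before` must be positive
#'   (normalization divides by it).
#' @param reference_source Free-text note on which reference was used.
#' @return A list of class `improvement_report` with fields `subject_id`,
#'   `raw_distance_before`, `raw_distance_after`, `error_before` (always 1),
#'   `error_after` and `improvement_pct`.
#' @export
improvement_report <- function(subject_id, raw_distance_before,
                               raw_distance_after,
                               reference_source = "") {
  if (!is.finite(raw_distance_before) || raw_distance_before <= 0) {
    stop("raw_distance_before must be > 0 (a pre-treatment condition ",
         "identical to the reference cannot be normalized)", call. = FALSE)
  }
  if (!is.finite(raw_distance_after) || raw_distance_after < 0) {
    stop("raw_distance_after must be >= 0", call. = FALSE)
  }
  error_after <- raw_distance_after / raw_distance_before
  structure(list(subject_id = as.character(subject_id),
                 raw_distance_before = raw_distance_before,
                 raw_distance_after = raw_distance_after,
                 error_before = 1,
                 error_after = error_after,
                 improvement_pct = improvement(error_after),
                 reference_source = reference_source),
            class = "improvement_report")
}

#' @export
print.improvement_report <- function(x, ...) {
  cat(sprintf("<improvement_report> subject %s: error before 1, after %.4f -> %d%% improvement\n",
              x$subject_id, x$error_after, x$improvement_pct))
  invisible(x)
}

#' Score one subject against the reference
#'
#' Computes the per-condition DTW distances of the before- and
#' after-treatment steps to the reference, normalizes to the before
#' condition (so `error_before = 1` by construction) and derives the
#' improvement percentage.
#'
#' @param reference Amplitude-normalized reference stance curve.
#' @param before_steps,after_steps Lists of amplitude-normalized step
#'   sequences for the two conditions.
#' @param subject_id Identifier.
#' @param aggregate Per-condition aggregation, `"mean"` or `"median"`.
#' @param reference_source Free-text note recorded in the report.
#' @return An [improvement_report()].
#' @export
score_subject <- function(reference, before_steps, after_steps, subject_id,
                          aggregate = c("mean", "median"),
                          reference_source = "") {
  aggregate <- match.arg(aggregate)
  improvement_report(
    subject_id = subject_id,
    raw_distance_before = condition_distance(reference, before_steps, aggregate),
    raw_distance_after = condition_distance(reference, after_steps, aggregate),
    reference_source = reference_source
  )
}

#' Tabulate improvement reports with summary statistics
#'
#' @param reports A list of [improvement_report()] objects (or a single
#'   one).
#' @return A list of class `improvement_batch`: `reports`, a data.frame
#'   with one row per subject in input order (columns `subject_id`,
#'   `raw_distance_before`, `raw_distance_after`, `error_before`,
#'   `error_after`, `improvement_pct`), and `summary`, a list with
#'   `min_improvement`, `max_improvement`, `mean_improvement`.
#' @examples
#' errs <- c(0.06, 0.09, 0.11)
#' reports <- lapply(seq_along(errs), function(i)
#'   improvement_report(i, 1, errs[i]))
#' batch_score(reports)$summary
#' @export
batch_score <- function(reports) {
  if (inherits(reports, "improvement_report")) reports <- list(reports)
  if (length(reports) == 0L) stop("at least one subject required", call. = FALSE)
  stopifnot(all(vapply(reports, inherits, logical(1), "improvement_report")))
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(subject_id = r$subject_id,
               raw_distance_before = r$raw_distance_before,
               raw_distance_after = r$raw_distance_after,
               error_before = r$error_before,
               error_after = r$error_after,
               improvement_pct = r$improvement_pct,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    reports = tab,
    summary = list(min_improvement = min(tab$improvement_pct),
                   max_improvement = max(tab$improvement_pct),
                   mean_improvement = mean(tab$improvement_pct))
  ), class = "improvement_batch")
}

#' @export
print.improvement_batch <- function(x, ...) {
  cat(sprintf("<improvement_batch> %d subject(s)\n", nrow(x$reports)))
  print(x$reports, row.names = FALSE)
  with(x$summary, cat(sprintf(
    "improvement: min %d%%, max %d%%, mean %.2f%%\n",
    min_improvement, max_improvement, mean_improvement)))
  invisible(x)
}
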