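subset_signal <- function(signal, idx) {
  t <- signal$time[idx]
  force_signal(time = t - t[1], force = ifelse(signal$gap[idx], NA_real_,
                                               signal$force[idx]),
               sample_rate = signal$sample_rate,
               foot_label = signal$foot_label, plate_id = signal$plate_id,
               subject_id = signal$subject_id)
}

#' Trim a recording to a time window
#'
#' Cuts away the beginning and end of a recording (e.g. walking onto and off
#' the plate area), keeping the half-open window `[keep_start, keep_end)`.
#' Time is re-based to start at 0.
#'
#' @param signal A [force_signal].
#' @param keep_start,keep_end Window bounds in seconds relative to the start
#'   of the recording, `0 <= keep_start < keep_end <= duration`.
#' @return The trimmed [force_signal].
#' @export
trim_signal <- function(signal, keep_start, keep_end) {
  stopifnot(inherits(signal, "force_signal"))
  if (!(keep_start >= 0 && keep_start < keep_end)) {
    stop("require 0 <= keep_start < keep_end", call. = FALSE)
  }
  rel <- signal$time - signal$time[1]
  idx <- which(rel >= keep_start - 1e-12 & rel < keep_end - 1e-12)
  if (length(idx) < 2L) stop("trim window leaves fewer than 2 samples",
                             call. = FALSE)
  subset_signal(signal, idx)
}

gap_runs <- function(gap) {
  r <- rle(gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts, end = ends, len = r$lengths, gap = r$values)
}

#' Fill or remove measurement gaps
#'
#' Short runs of missing force samples (length `<= max_gap`) are filled by
#' linear interpolation between the flanking valid samples. Longer runs
#' split the recording; the longest contiguous valid stretch is returned.
#' The output contains no gaps.
#'
#' @param signal A [force_signal], possibly with gap samples.
#' @param max_gap Longest gap run (in samples) that may be interpolated.
#' @return A gap-free [force_signal].
#' @export
remove_gaps <- function(signal, max_gap = 5L) {
  stopifnot(inherits(signal, "force_signal"), max_gap >= 0)
  if (all(signal$gap)) stop("signal is entirely gaps", call. = FALSE)
  if (!any(signal$gap)) return(signal)

  force <- signal$force
  gap <- signal$gap
  runs <- gap_runs(gap)
  # interpolate interior short gaps (runs at the edges have no flank on one
  # side and are treated as long gaps)
  for (i in seq_len(nrow(runs))) {
    if (!runs$gap[i] || runs$len[i] > max_gap) next
    lo <- runs$start[i] - 1L
    hi <- runs$end[i] + 1L
    if (lo < 1L || hi > length(force)) next
    sel <- runs$start[i]:runs$end[i]
    force[sel] <- stats::approx(x = c(lo, hi), y = force[c(lo, hi)],
                                xout = sel)$y
    gap[sel] <- FALSE
  }
  if (!any(gap)) {
    return(force_signal(signal$time, force, signal$sample_rate,
                        signal$foot_label, signal$plate_id,
                        signal$subject_id))
  }
  # split at remaining (long) gaps, keep the longest valid stretch
  runs <- gap_runs(gap)
  valid <- runs[!runs$gap, , drop = FALSE]
  best <- valid[which.max(valid$len), ]
  idx <- best$start:best$end
  if (length(idx) < 2L) stop("longest gap-free stretch has < 2 samples",
                             call. = FALSE)
  out <- signal
  out$force <- force
  out$gap <- gap
  subset_signal(out, idx)
}

#' Detect stance-phase steps in a force trace
#'
#' Finds maximal contiguous intervals where the force exceeds
#' `threshold_fraction` of the global peak — the conventional relative
#' contact-threshold definition of foot contact — and keeps those whose
#' duration lies within `[min_duration, max_duration]`. Intervals outside
#' the band (e.g. a double contact or a partial step at a recording edge)
#' are excluded and reported in the `rejected` attribute, mirroring how an
#' improper first contact is discarded from a trial.
#'
#' @param signal A gap-free [force_signal].
#' @param threshold_fraction Contact threshold as a fraction of the global
#'   peak force, in (0, 1). Default 0.05.
#' @param min_duration,max_duration Stance-duration band in seconds
#'   (defaults 0.3 and 1.5, a physiological stance range).
#' @return A list of step segments, each a list with `start_index`,
#'   `end_index` (0-based, half-open), `duration` (s), `peak_force` (N),
#'   `foot_label` and `parent` (the input signal). Rejected intervals are
#'   attached as attribute `"rejected"`.
#' @export
detect_steps <- function(signal, threshold_fraction = 0.05,
                         min_duration = 0.3, max_duration = 1.5) {
  stopifnot(inherits(signal, "force_signal"))
  if (any(signal$gap)) stop("detect_steps requires a gap-free signal (run remove_gaps first)",
                            call. = FALSE)
  if (!(threshold_fraction > 0 && threshold_fraction < 1)) {
    stop("threshold_fraction must be in (0, 1)", call. = FALSE)
  }
  peak <- max(signal$force)
  if (peak <= 0) return(structure(list(), rejected = list()))
  above <- signal$force > threshold_fraction * peak
  runs <- gap_runs(above)
  runs <- runs[runs$gap, , drop = FALSE]  # runs where 'above' is TRUE
  segs <- list()
  rejected <- list()
  for (i in seq_len(nrow(runs))) {
    s0 <- runs$start[i] - 1L            # 0-based inclusive
    e0 <- runs$end[i]                   # 0-based exclusive
    dur <- (e0 - s0) / signal$sample_rate
    seg <- list(parent = signal, start_index = s0, end_index = e0,
                duration = dur,
                peak_force = max(signal$force[(s0 + 1L):e0]),
                foot_label = signal$foot_label)
    class(seg) <- "step_segment"
    if (dur >= min_duration && dur <= max_duration) {
      segs[[length(segs) + 1L]] <- seg
    } else {
      rejected[[length(rejected) + 1L]] <- seg
    }
  }
  structure(segs, rejected = rejected)
}

#' @export
print.step_segment <- function(x, ...) {
  cat(sprintf("<step_segment> samples [%d, %d), %.3f s, peak %.1f N, foot=%s\n",
              x$start_index, x$end_index, x$duration, x$peak_force,
              x$foot_label))
  invisible(x)
}

segment_forces <- function(segment) {
  segment$parent$force[(segment$start_index + 1L):segment$end_index]
}

#' Amplitude-normalize a step segment
#'
#' Expresses a step's force samples in dimensionless units so that subjects
#' of different mass are comparable to a reference recorded from a different
#' person: in multiples of body weight (BW) when `body_weight` is given,
#' otherwise relative to the segment's own peak (peak = 1).
#'
#' @param segment A step segment from [detect_steps()].
#' @param body_weight Body weight in newtons, or `NULL` for peak
#'   normalization.
#' @return A numeric vector of dimensionless samples.
#' @export
normalize_amplitude <- function(segment, body_weight = NULL) {
  stopifnot(inherits(segment, "step_segment"))
  f <- segment_forces(segment)
  if (!is.null(body_weight)) {
    if (!(is.numeric(body_weight) && body_weight > 0)) {
      stop("body_weight must be > 0", call. = FALSE)
    }
    return(f / body_weight)
  }
  pk <- max(f)
  if (pk <= 0) stop("cannot peak-normalize a segment with non-positive peak",
                    call. = FALSE)
  f / pk
}

#' Moving-average smoothing
#'
#' Centered moving average with an odd window; near the ends the window is
#' clamped to the available samples (so the first sample of a window-3
#' average is the mean of samples 1 and 2). `window = 1` is the identity.
#' High-frequency plate noise can alternatively be left in and
#' removed by trimming to clean movements; smoothing is therefore off by
#' default in the pipeline.
#'
#' @param signal A gap-free [force_signal].
#' @param window Odd window length in samples.
#' @return The smoothed [force_signal].
#' @export
smooth_signal <- function(signal, window = 1L) {
  stopifnot(inherits(signal, "force_signal"))
  if (window %% 2L == 0L || window < 1L) {
    stop("window must be odd and >= 1", call. = FALSE)
  }
  if (any(signal$gap)) stop("smooth_signal requires a gap-free signal",
                            call. = FALSE)
  if (window == 1L) return(signal)
  n <- length(signal$force)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, signal$force))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  force_signal(signal$time, out, signal$sample_rate, signal$foot_label,
               signal$plate_id, signal$subject_id)
}
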