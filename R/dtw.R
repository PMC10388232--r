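#' Local distance between two samples
#'
#' The pointwise cost used by the DTW recurrence: the absolute difference
#' `|r_k - t_l|` between a reference sample and a measured sample.
#'
#' @param r_k,t_l Finite numeric sample values (vectorized).
#' @return `|r_k - t_l|`.
#' @export
local_distance <- function(r_k, t_l) {
  if (any(!is.finite(r_k)) || any(!is.finite(t_l))) {
    stop("local_distance requires finite inputs", call. = FALSE)
  }
  abs(r_k - t_l)
}

#' Dynamic time warping distance and optimal alignment
#'
#' Computes the exact, unconstrained DTW distance between a reference
#' sequence `r[1:n]` and a measured sequence `t[1:m]` with absolute-value
#' local cost. The accumulated cost satisfies
#' `F(k, l) = |r_k - t_l| + min(F(k-1, l), F(k, l-1), F(k-1, l-1))`
#' with `F(0, 0) = 0` and +Inf sentinels along the first row and column;
#' the distance is `F(n, m)` and the optimal warping path is recovered by
#' backtracking the argmin predecessor from `(n, m)` to `(1, 1)` (ties:
#' diagonal, then the predecessor reducing `k`, then the one reducing `l`).
#' No warping window, slope constraint or path-length normalization is
#' applied; sequences of different lengths are compared directly.
#'
#' @param r,t Non-empty finite numeric sequences.
#' @param keep_matrix Retain the full accumulated-cost matrix and warping
#'   path in the result. When `FALSE` only the distance is computed, with a
#'   two-row recurrence that returns the identical value.
#' @return An object of class `dtw_result`: a list with `distance`,
#'   `n`, `m`, and (when `keep_matrix = TRUE`) `matrix` (the (n+1) x (m+1)
#'   accumulated-cost matrix including sentinels) and `path` (a 2-column
#'   matrix of 1-based `(k, l)` index pairs from `(1, 1)` to `(n, m)`).
#' @examples
#' d <- dtw(c(1, 2, 3), c(2, 3, 4))
#' d$distance  # 2
#' d$path
#' @export
dtw <- function(r, t, keep_matrix = TRUE) {
  r <- as.numeric(r)
  t <- as.numeric(t)
  if (length(r) == 0L || length(t) == 0L) {
    stop("dtw requires non-empty sequences", call. = FALSE)
  }
  if (any(!is.finite(r)) || any(!is.finite(t))) {
    stop("dtw requires finite sequences", call. = FALSE)
  }
  if (!keep_matrix) {
    res <- list(distance = .dtw_distance_only(r, t),
                matrix = NULL, path = NULL,
                n = length(r), m = length(t))
    class(res) <- "dtw_result"
    return(res)
  }
  F <- .dtw_fill(r, t)
  path <- .dtw_backtrack(F)
  colnames(path) <- c("k", "l")
  res <- list(distance = F[length(r) + 1L, length(t) + 1L],
              matrix = F, path = path, n = length(r), m = length(t))
  class(res) <- "dtw_result"
  res
}

#' DTW distance only
#'
#' Convenience wrapper around [dtw()] that skips matrix and path recovery;
#' used throughout the scoring pipeline where only distances are needed.
#'
#' @inheritParams dtw
#' @return The DTW distance, a non-negative scalar.
#' @export
dtw_distance <- function(r, t) {
  dtw(r, t, keep_matrix = FALSE)$distance
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> distance %.6g between sequences of length %d and %d\n",
              x$distance, x$n, x$m))
  if (!is.null(x$path)) {
    cat(sprintf("  warping path: %d steps from (1,1) to (%d,%d)\n",
                nrow(x$path), x$n, x$m))
  }
  invisible(x)
}

#' Brute-force DTW oracle
#'
#' Independent check of [dtw()] for short sequences: explicitly enumerates
#' every monotone warping path from `(1, 1)` to `(n, m)` with steps
#' `(+1, 0)`, `(0, +1)`, `(+1, +1)` and returns the minimum total local
#' cost. Exponential in the sequence lengths, hence the `max_len` guard.
#'
#' @inheritParams dtw
#' @param max_len Maximum allowed sequence length (default 7).
#' @return The minimum path cost.
#' @export
dtw_brute_force <- function(r, t, max_len = 7L) {
  r <- as.numeric(r)
  t <- as.numeric(t)
  n <- length(r)
  m <- length(t)
  if (n == 0L || m == 0L) stop("non-empty sequences required", call. = FALSE)
  if (n > max_len || m > max_len) {
    stop("sequence longer than max_len = ", max_len, call. = FALSE)
  }
  best <- Inf
  recurse <- function(k, l, acc) {
    acc <- acc + abs(r[k] - t[l])
    if (k == n && l == m) {
      if (acc < best) best <<- acc
      return(invisible(NULL))
    }
    if (k < n && l < m) recurse(k + 1L, l + 1L, acc)
    if (k < n) recurse(k + 1L, l, acc)
    if (l < m) recurse(k, l + 1L, acc)
    invisible(NULL)
  }
  recurse(1L, 1L, 0)
  best
}

#' Sum of local costs along a warping path
#'
#' @param r,t The sequences passed to [dtw()].
#' @param path The warping path, a 2-column matrix of `(k, l)` pairs.
#' @return The accumulated local cost along the path.
#' @keywords internal
#' @export
path_cost <- function(r, t, path) {
  sum(abs(r[path[, 1]] - t[path[, 2]]))
}
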