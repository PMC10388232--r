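#' Construct a force-plate signal
#'
#' A `force_signal` is a uniformly sampled vertical ground-reaction-force
#' (GRF) time series from a single plate/foot: time in seconds, force in
#' newtons (positive = compression). Samples whose force could not be
#' measured are carried as explicit gaps (`NA` force plus a logical mask),
#' never silently dropped or interpolated at construction time.
#'
#' @param time Numeric vector of sample times in seconds, strictly
#'   increasing with uniform spacing.
#' @param force Numeric vector of vertical forces in newtons; `NA` marks a
#'   gap (missing marker).
#' @param sample_rate Sampling rate in Hz. If `NULL` it is inferred from the
#'   median time spacing. Must agree with the median spacing within 1%.
#' @param foot_label One of `"left"`, `"right"`, `"unknown"`.
#' @param plate_id,subject_id Free-text identifiers.
#' @return An object of class `force_signal` with fields `time`, `force`,
#'   `gap` (logical mask), `sample_rate`, `foot_label`, `plate_id`,
#'   `subject_id`.
#' @examples
#' s <- force_signal(time = seq(0, 0.99, by = 0.01), force = rep(100, 100))
#' s$sample_rate
#' @export
force_signal <- function(time, force, sample_rate = NULL,
                         foot_label = "unknown", plate_id = "",
                         subject_id = "") {
  time <- as.numeric(time)
  force <- as.numeric(force)
  if (length(time) != length(force)) {
    stop("'time' and 'force' must have equal length", call. = FALSE)
  }
  if (length(time) < 2L) {
    stop("a force signal needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(time) || any(!is.finite(time))) {
    stop("'time' must be finite", call. = FALSE)
  }
  dt <- diff(time)
  if (any(dt <= 0)) {
    stop("'time' must be strictly increasing", call. = FALSE)
  }
  med_dt <- stats::median(dt)
  if (any(abs(dt - med_dt) > 0.01 * med_dt + 1e-12)) {
    stop("'time' must be uniformly spaced (within 1% of the median step)",
         call. = FALSE)
  }
  if (is.null(sample_rate)) sample_rate <- 1 / med_dt
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      sample_rate <= 0) {
    stop("'sample_rate' must be a positive scalar", call. = FALSE)
  }
  if (abs(sample_rate - 1 / med_dt) > 0.01 * sample_rate) {
    stop("'sample_rate' inconsistent with the time spacing (>1%)",
         call. = FALSE)
  }
  gap <- is.na(force) | !is.finite(force)
  force[gap] <- NA_real_
  foot_label <- match.arg(foot_label, c("left", "right", "unknown"))
  structure(
    list(time = time, force = force, gap = gap,
         sample_rate = sample_rate, foot_label = foot_label,
         plate_id = as.character(plate_id),
         subject_id = as.character(subject_id)),
    class = "force_signal"
  )
}

#' @export
print.force_signal <- function(x, ...) {
  cat(sprintf(
    "<force_signal> %d samples @ %.6g Hz (%.3f s), foot=%s%s%s\n",
    length(x$force), x$sample_rate,
    length(x$force) / x$sample_rate, x$foot_label,
    if (nzchar(x$subject_id)) paste0(", subject=", x$subject_id) else "",
    if (any(x$gap)) sprintf(", %d gap samples", sum(x$gap)) else ""))
  rng <- range(x$force, na.rm = !all(x$gap))
  if (!all(x$gap)) cat(sprintf("  force range: [%.1f, %.1f] N\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
length.force_signal <- function(x) length(x$force)

detect_delimiter <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) == 0L) return(",")
  counts <- vapply(c(",", "\t", ";"), function(d) {
    lengths(regmatches(line, gregexpr(d, line, fixed = TRUE)))
  }, integer(1))
  names(counts)[which.max(counts)]
}

#' Read a force-plate trace from delimited text
#'
#' Reads one vertical-GRF trace (time in seconds, force in newtons) from a
#' CSV/TSV/semicolon-delimited file with a header row. Rows whose force cell
#' is empty or unparseable become flagged gaps, never silent drops, so the
#' number of rows in equals the number of samples out.
#'
#' @param path Path to the file.
#' @param column_spec Named list mapping the roles `time` and `force` (and
#'   optionally `foot`, `plate`, `subject`) to column names in the file.
#' @param force_scale Multiplicative factor applied to the force column
#'   (e.g. to convert kgf to N); default 1, i.e. the file is in newtons.
#' @return A [force_signal].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("time,force", "0,0", "0.01,100", "0.02,400"), f)
#' read_force_trace(f)
#' @export
read_force_trace <- function(path,
                             column_spec = list(time = "time", force = "force"),
                             force_scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_delimiter(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          strip.white = TRUE)
  spec <- utils::modifyList(list(time = "time", force = "force",
                                 foot = "foot", plate = "plate",
                                 subject = "subject"),
                            as.list(column_spec))
  pick <- function(role, required = FALSE) {
    col <- spec[[role]]
    if (is.numeric(col)) {
      if (col >= 1 && col <= ncol(dt)) return(dt[[col]])
      if (required) stop("column index out of range for '", role, "'",
                         call. = FALSE)
      return(NULL)
    }
    if (col %in% names(dt)) return(dt[[col]])
    if (required) stop("missing required column '", col, "' in ", path,
                       call. = FALSE)
    NULL
  }
  time_raw <- pick("time", required = TRUE)
  force_raw <- pick("force", required = TRUE)
  time <- suppressWarnings(as.numeric(time_raw))
  if (anyNA(time)) stop("non-numeric values in time column", call. = FALSE)
  force <- suppressWarnings(as.numeric(force_raw)) * force_scale
  if (length(force) < 2L || sum(!is.na(force)) < 2L) {
    stop("fewer than 2 valid samples in ", path, call. = FALSE)
  }
  foot <- pick("foot")
  foot_label <- if (!is.null(foot) && nzchar(foot[1])) {
    tolower(foot[1])
  } else "unknown"
  if (!foot_label %in% c("left", "right")) foot_label <- "unknown"
  force_signal(
    time = time, force = force, foot_label = foot_label,
    plate_id = if (!is.null(p <- pick("plate"))) p[1] else "",
    subject_id = if (!is.null(s <- pick("subject"))) s[1] else ""
  )
}

#' Write a force-plate trace to CSV
#'
#' Serializes a [force_signal] so that `read_force_trace(write_force_trace(s))`
#' reproduces time, force and gap flags to 1e-6. Gaps are written as empty
#' cells.
#'
#' @param signal A [force_signal].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_force_trace <- function(signal, path) {
  stopifnot(inherits(signal, "force_signal"))
  df <- data.frame(
    time = sprintf("%.6f", signal$time),
    force = ifelse(signal$gap, "", sprintf("%.6f", signal$force)),
    stringsAsFactors = FALSE
  )
  if (signal$foot_label != "unknown") df$foot <- signal$foot_label
  if (nzchar(signal$plate_id)) df$plate <- signal$plate_id
  if (nzchar(signal$subject_id)) df$subject <- signal$subject_id
  ok <- tryCatch({
    data.table::fwrite(df, path, quote = FALSE)
    TRUE
  }, error = function(e) {
    stop("cannot write to ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

#' Read a cohort demographics table
#'
#' Reads a delimited table with columns `id`, `sex`, `age`, `bmi` and
#' optionally `body_weight` (newtons). Sex tokens are normalized
#' case-insensitively to `"female"`/`"male"` (initials `f`/`m` accepted).
#'
#' @param path Path to the cohort file.
#' @return A data.frame with one row per volunteer and columns `id` (integer),
#'   `sex` (factor, levels female/male), `age`, `bmi` and `body_weight`
#'   (`NA` when absent).
#' @examples
#' cohort <- read_cohort_table(
#'   system.file("extdata", "tka_cohort_demographics.csv", package = "gaitdtw"))
#' nrow(cohort)
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- detect_delimiter(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, strip.white = TRUE)
  need <- c("id", "sex", "age", "bmi")
  names(dt) <- tolower(names(dt))
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("cohort table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(dt) == 0L) {
    return(data.frame(id = integer(), sex = factor(levels = c("female", "male")),
                      age = numeric(), bmi = numeric(),
                      body_weight = numeric()))
  }
  sex_raw <- tolower(trimws(as.character(dt$sex)))
  sex <- ifelse(sex_raw %in% c("female", "f"), "female",
                ifelse(sex_raw %in% c("male", "m"), "male", NA_character_))
  if (anyNA(sex)) {
    stop("unknown sex token(s): ",
         paste(unique(sex_raw[is.na(sex)]), collapse = ", "), call. = FALSE)
  }
  age <- suppressWarnings(as.numeric(dt$age))
  bmi <- suppressWarnings(as.numeric(dt$bmi))
  if (anyNA(age) || any(age <= 0)) stop("age must be numeric and > 0", call. = FALSE)
  if (anyNA(bmi) || any(bmi <= 0)) stop("bmi must be numeric and > 0", call. = FALSE)
  bw <- if ("body_weight" %in% names(dt)) {
    suppressWarnings(as.numeric(dt$body_weight))
  } else rep(NA_real_, nrow(dt))
  data.frame(id = as.integer(dt$id),
             sex = factor(sex, levels = c("female", "male")),
             age = age, bmi = bmi, body_weight = bw)
}
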