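#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis pipeline in one
#' validated list. A YAML file with any subset of these keys can be loaded
#' with [load_config()]; explicit arguments win over file values.
#'
#' @param trim_start,trim_end Optional trim window in seconds
#'   ([trim_signal()]); `NULL` disables trimming.
#' @param max_gap Longest gap run (samples) interpolated by
#'   [remove_gaps()].
#' @param threshold_fraction,min_duration,max_duration Step-detection
#'   parameters ([detect_steps()]).
#' @param smoothing_window Odd moving-average window in samples; 1 (the
#'   default) disables smoothing.
#' @param aggregate Per-condition distance aggregation, `"mean"` or
#'   `"median"`.
#' @param reference `"synthetic"` for the built-in healthy curve, or a path
#'   to a reference force trace CSV.
#' @param obesity_bmi_threshold BMI cut-off for [summarize_cohort()].
#' @param seed Integer seed for all randomness in a run.
#' @param out_dir Output directory for reports and logs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(trim_start = NULL, trim_end = NULL,
                            max_gap = 5L,
                            threshold_fraction = 0.05,
                            min_duration = 0.3, max_duration = 1.5,
                            smoothing_window = 1L,
                            aggregate = "mean",
                            reference = "synthetic",
                            obesity_bmi_threshold = 28,
                            seed = 1L,
                            out_dir = ".") {
  stopifnot(max_gap >= 0, threshold_fraction > 0, threshold_fraction < 1,
            min_duration > 0, max_duration > min_duration,
            smoothing_window >= 1, smoothing_window %% 2 == 1,
            aggregate %in% c("mean", "median"))
  structure(list(trim_start = trim_start, trim_end = trim_end,
                 max_gap = as.integer(max_gap),
                 threshold_fraction = threshold_fraction,
                 min_duration = min_duration, max_duration = max_duration,
                 smoothing_window = as.integer(smoothing_window),
                 aggregate = aggregate, reference = reference,
                 obesity_bmi_threshold = obesity_bmi_threshold,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys are [pipeline_config()]
#'   arguments.
#' @param ... Overrides; explicit arguments win over file values.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path = NULL, ...) {
  vals <- if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    yaml::read_yaml(path)
  } else list()
  vals <- utils::modifyList(vals, list(...))
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

# reference stance curve in BW units
reference_curve <- function(config, params = gait_params()) {
  if (identical(config$reference, "synthetic")) {
    return(reference_step(params, config$threshold_fraction))
  }
  sig <- read_force_trace(config$reference)
  sig <- remove_gaps(sig, config$max_gap)
  if (config$smoothing_window > 1L) {
    sig <- smooth_signal(sig, config$smoothing_window)
  }
  steps <- detect_steps(sig, config$threshold_fraction,
                        config$min_duration, config$max_duration)
  if (length(steps) == 0L) {
    stop("no valid step found in reference trace ", config$reference,
         call. = FALSE)
  }
  normalize_amplitude(steps[[1]])
}

# read -> trim -> de-gap -> (smooth) -> segment -> normalize, for one file
extract_steps <- function(path, config, body_weight = NULL) {
  sig <- read_force_trace(path)
  if (!is.null(config$trim_start) && !is.null(config$trim_end)) {
    sig <- trim_signal(sig, config$trim_start, config$trim_end)
  }
  sig <- remove_gaps(sig, config$max_gap)
  if (config$smoothing_window > 1L) {
    sig <- smooth_signal(sig, config$smoothing_window)
  }
  steps <- detect_steps(sig, config$threshold_fraction,
                        config$min_duration, config$max_duration)
  lapply(steps, normalize_amplitude, body_weight = body_weight)
}

read_manifest <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1L) {
    if (!file.exists(manifest)) {
      stop("manifest file not found: ", manifest, call. = FALSE)
    }
    manifest <- data.table::fread(manifest, data.table = FALSE)
  }
  stopifnot(is.data.frame(manifest))
  names(manifest) <- tolower(names(manifest))
  need <- c("subject_id", "condition", "path")
  if (nrow(manifest) == 0L || !all(need %in% names(manifest))) {
    stop("manifest needs >= 1 row and columns subject_id, condition, path",
         call. = FALSE)
  }
  manifest$condition <- tolower(manifest$condition)
  if (!all(manifest$condition %in% c("before", "after"))) {
    stop("manifest conditions must be 'before' or 'after'", call. = FALSE)
  }
  if (!"body_weight" %in% names(manifest)) {
    manifest$body_weight <- NA_real_
  }
  manifest
}

#' Run the full gait-improvement analysis
#'
#' Executes read, trim, gap removal, optional smoothing, step detection,
#' amplitude normalization, DTW against the reference and normalized
#' scoring for every subject in a manifest, and writes `report.csv` and a
#' run log to the configured output directory. A subject whose files fail
#' is logged and skipped; the run only fails if every subject fails.
#'
#' @param config A [pipeline_config()].
#' @param manifest A data.frame (or path to a CSV) with columns
#'   `subject_id`, `condition` (`before`/`after`), `path` and optionally
#'   `body_weight` (newtons; when absent, steps are peak-normalized).
#' @return The [batch_score()] result, invisibly. Side effects:
#'   `<out_dir>/report.csv` and `<out_dir>/run_log.txt`.
#' @export
run_analyze <- function(config, manifest) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- read_manifest(manifest)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- c(
    sprintf("gaitdtw %s analyze run, %s",
            as.character(utils::packageVersion("gaitdtw")),
            format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("config: ", jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                        null = "null")))
  reference <- reference_curve(config)
  ref_source <- if (identical(config$reference, "synthetic")) {
    "synthetic healthy curve"
  } else config$reference

  reports <- list()
  for (sid in unique(manifest$subject_id)) {
    rows <- manifest[manifest$subject_id == sid, , drop = FALSE]
    bw <- rows$body_weight[1]
    if (is.na(bw)) bw <- NULL
    rep <- tryCatch({
      steps_for <- function(cond) {
        paths <- rows$path[rows$condition == cond]
        if (length(paths) == 0L) stop("no '", cond, "' files for subject ", sid)
        unlist(lapply(paths, extract_steps, config = config,
                      body_weight = bw), recursive = FALSE)
      }
      score_subject(reference, steps_for("before"), steps_for("after"),
                    subject_id = sid, aggregate = config$aggregate,
                    reference_source = ref_source)
    }, error = function(e) {
      log_lines <<- c(log_lines,
                      sprintf("SKIP subject %s: %s", sid, conditionMessage(e)))
      NULL
    })
    if (!is.null(rep)) {
      reports[[length(reports) + 1L]] <- rep
      log_lines <- c(log_lines,
                     sprintf("subject %s: improvement %d%%", sid,
                             rep$improvement_pct))
    }
  }
  writeLines(log_lines, log_path)
  if (length(reports) == 0L) {
    stop("all subjects failed; see ", log_path, call. = FALSE)
  }
  batch <- batch_score(reports)
  data.table::fwrite(batch$reports, file.path(config$out_dir, "report.csv"))
  invisible(batch)
}

#' Simulate a cohort of before/after trials to disk
#'
#' Writes one before- and one after-treatment trace CSV per synthetic
#' subject (readable by [read_force_trace()]), a JSON sidecar per subject
#' with the ground truth (severities, step windows, seeds), and
#' `manifest.csv` suitable for [run_analyze()]. Idempotent for a fixed
#' config seed.
#'
#' @param config A [pipeline_config()]; `config$seed` drives everything.
#' @param n_subjects Number of subjects.
#' @param severity_before_range,severity_after_range Ranges from which
#'   per-subject true severities are drawn uniformly.
#' @param params A [gait_params()] shared by the cohort.
#' @param n_steps Steps per trial.
#' @return Path to the written manifest, invisibly.
#' @export
run_simulate <- function(config, n_subjects = 18L,
                         severity_before_range = c(0.7, 0.9),
                         severity_after_range = c(0.03, 0.1),
                         params = gait_params(), n_steps = 10L) {
  stopifnot(inherits(config, "pipeline_config"))
  if (n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  draws <- with_local_seed(config$seed, {
    list(sev_b = stats::runif(n_subjects, severity_before_range[1],
                              severity_before_range[2]),
         sev_a = stats::runif(n_subjects, severity_after_range[1],
                              severity_after_range[2]),
         seeds = sample.int(.Machine$integer.max - 1L, n_subjects))
  })
  rows <- list()
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", i)
    pair <- synth_subject_pair(params, draws$sev_b[i], draws$sev_a[i],
                               n_steps = n_steps, seed = draws$seeds[i])
    for (cond in c("before", "after")) {
      trial <- pair[[cond]]
      trial$signal$subject_id <- sid
      f <- file.path(config$out_dir, sprintf("%s_%s.csv", sid, cond))
      write_force_trace(trial$signal, f)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, condition = cond, path = f,
        body_weight = params$body_weight)
    }
    truth <- list(subject_id = sid,
                  severity_before = draws$sev_b[i],
                  severity_after = draws$sev_a[i],
                  seed = draws$seeds[i],
                  body_weight = params$body_weight,
                  windows_before = pair$before$true_step_windows,
                  windows_after = pair$after$true_step_windows)
    jsonlite::write_json(truth,
                         file.path(config$out_dir,
                                   sprintf("%s_truth.json", sid)),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest_path <- file.path(config$out_dir, "manifest.csv")
  data.table::fwrite(do.call(rbind, rows), manifest_path)
  invisible(manifest_path)
}
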