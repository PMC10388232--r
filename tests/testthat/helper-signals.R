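# Shared fixture builders: everything is generated in code at test time.

# uniformly sampled signal from a force vector
make_signal <- function(force, rate = 100, ...) {
  force_signal(time = (seq_along(force) - 1) / rate, force = force,
               sample_rate = rate, ...)
}

# zero baseline with rectangular contacts: `contacts` is a list of
# c(start_s, duration_s, level_N); returns the signal plus the exact
# 0-based half-open sample windows of each contact
make_contact_signal <- function(contacts, total_s = 10, rate = 100) {
  n <- total_s * rate
  f <- numeric(n)
  windows <- matrix(NA_integer_, length(contacts), 2)
  for (i in seq_along(contacts)) {
    s0 <- round(contacts[[i]][1] * rate)
    len <- round(contacts[[i]][2] * rate)
    f[(s0 + 1):(s0 + len)] <- contacts[[i]][3]
    windows[i, ] <- c(s0, s0 + len)
  }
  list(signal = make_signal(f, rate), windows = windows)
}

# write a signal to a temp CSV and return the path (cleaned up by caller's
# withr/tempfile semantics; files live in tempdir())
temp_trace <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# a hand-built step_segment (bypassing detect_steps) for edge cases
manual_segment <- function(signal, start_index, end_index) {
  structure(list(parent = signal, start_index = start_index,
                 end_index = end_index,
                 duration = (end_index - start_index) / signal$sample_rate,
                 peak_force = max(signal$force[(start_index + 1):end_index]),
                 foot_label = signal$foot_label),
            class = "step_segment")
}

table2_errors <- function() {
  read.csv(system.file("extdata", "tka_normalized_errors.csv",
                       package = "gaitdtw"))
}

cohort_fixture <- function() {
  read_cohort_table(system.file("extdata", "tka_cohort_demographics.csv",
                                package = "gaitdtw"))
}
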