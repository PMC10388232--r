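#' Summarize cohort demographics
#'
#' Derives the descriptive statistics usually reported for a surgical
#' cohort: sample size, mean and sample standard deviation of age
#' (`n - 1` denominator), integer-rounded sex percentages, the obesity
#' rate at a configurable BMI threshold, and the share of women among the
#' obese volunteers.
#'
#' The default obesity threshold is 28 kg/m2 rather than the WHO's 30;
#' the bundled example cohort classifies its four heaviest volunteers
#' (BMI 28-30.5) as obese, which only a threshold of 28 reproduces. The
#' threshold is a parameter, so the WHO convention is one argument away.
#'
#' @param cohort A data.frame as returned by [read_cohort_table()]
#'   (columns `sex`, `age`, `bmi`).
#' @param obesity_bmi_threshold Obesity cut-off in kg/m2; obesity is
#'   `bmi >= threshold`.
#' @return A list of class `cohort_summary`: `n`, `mean_age`, `sd_age`,
#'   `pct_female`, `pct_male`, `pct_obese`, `pct_obese_female` (0 with
#'   `obese_subgroup_empty = TRUE` when nobody is obese) and
#'   `obesity_bmi_threshold`.
#' @examples
#' cohort <- read_cohort_table(
#'   system.file("extdata", "tka_cohort_demographics.csv", package = "gaitdtw"))
#' summarize_cohort(cohort)
#' @export
summarize_cohort <- function(cohort, obesity_bmi_threshold = 28) {
  stopifnot(is.data.frame(cohort),
            all(c("sex", "age", "bmi") %in% names(cohort)))
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  female <- cohort$sex == "female"
  obese <- cohort$bmi >= obesity_bmi_threshold
  empty_obese <- !any(obese)
  structure(list(
    n = nrow(cohort),
    mean_age = mean(cohort$age),
    sd_age = stats::sd(cohort$age),
    pct_female = as.integer(round(100 * mean(female))),
    pct_male = as.integer(round(100 * mean(!female))),
    pct_obese = as.integer(round(100 * mean(obese))),
    pct_obese_female = if (empty_obese) 0L else
      as.integer(round(100 * mean(female[obese]))),
    obese_subgroup_empty = empty_obese,
    obesity_bmi_threshold = obesity_bmi_threshold
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d\n", x$n))
  cat(sprintf("  age: mean %.2f, sd %.2f years\n", x$mean_age, x$sd_age))
  cat(sprintf("  sex: %d%% female / %d%% male\n", x$pct_female, x$pct_male))
  cat(sprintf("  obesity (BMI >= %g): %d%%", x$obesity_bmi_threshold,
              x$pct_obese))
  if (x$obese_subgroup_empty) {
    cat(" (no obese volunteers; female share undefined, reported as 0)\n")
  } else {
    cat(sprintf(", of whom %d%% female\n", x$pct_obese_female))
  }
  invisible(x)
}

#' Cohort summary as a one-row data.frame
#'
#' @param x A `cohort_summary`.
#' @param ... Unused.
#' @return A one-row data.frame, convenient for CSV export.
#' @export
as.data.frame.cohort_summary <- function(x, ...) {
  data.frame(n = x$n, mean_age = x$mean_age, sd_age = x$sd_age,
             pct_female = x$pct_female, pct_male = x$pct_male,
             pct_obese = x$pct_obese, pct_obese_female = x$pct_obese_female,
             obese_subgroup_empty = x$obese_subgroup_empty,
             obesity_bmi_threshold = x$obesity_bmi_threshold)
}
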