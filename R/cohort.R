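#' Reference cohort of knee-arthroplasty patients
#'
#' Characteristics of the 20-patient total-knee-replacement cohort the
#' grading statistics are anchored to: age, sex, body-mass index, presence
#' of rheumatoid/spondylarthritis, the patient-level mean OARSI cartilage
#' grade (averaged over that patient's osteochondral samples by three
#' raters), and which knee was operated. Bundled as a plain CSV under
#' `inst/extdata` so cohort-level summaries are reproducible at the desk.
#'
#' @return A tibble with 20 rows and columns `patient_id`, `age_years`,
#'   `sex`, `bmi`, `rheumatoid_arthritis`, `mean_oarsi`, `operated_knee`.
#' @examples
#' cohort <- cohort_patients()
#' mean(cohort$age_years)   # 74.5
#' mean(cohort$mean_oarsi)  # 4.07
#' @export
cohort_patients <- function() {
  path <- system.file("extdata", "cohort_patients.csv",
                      package = "subchondral", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Summarise a patient cohort table
#'
#' Computes the cohort-level descriptive statistics reported for a grading
#' study: number of patients, mean age with range, and the mean of the
#' per-patient mean OARSI scores (with SD).
#'
#' @param cohort A tibble with at least `age_years` and `mean_oarsi`
#'   columns, as returned by [cohort_patients()].
#' @return A one-row tibble with columns `n_patients`, `mean_age`,
#'   `age_min`, `age_max`, `mean_oarsi`, `sd_oarsi`.
#' @examples
#' summarize_cohort(cohort_patients())
#' @export
summarize_cohort <- function(cohort) {
  required <- c("age_years", "mean_oarsi")
  missing <- setdiff(required, names(cohort))
  if (length(missing) > 0) {
    stop("cohort table is missing columns: ", paste(missing, collapse = ", "))
  }
  tibble::tibble(
    n_patients = nrow(cohort),
    mean_age = mean(cohort$age_years),
    age_min = min(cohort$age_years),
    age_max = max(cohort$age_years),
    mean_oarsi = mean(cohort$mean_oarsi),
    sd_oarsi = stats::sd(cohort$mean_oarsi)
  )
}
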