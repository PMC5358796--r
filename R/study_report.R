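signif_marks <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Full statistical report of a grading study
#'
#' Runs the complete statistical layer on a study table: per-bone-grade
#' mean OARSI, per-grade layer-thickness summaries (mean +/- SE),
#' subchondral plate fold changes against grade 0, group tests of the two
#' LBP interface descriptors across bone grades 0--2 (grade 3 sections
#' have a smooth, worn plate surface and are excluded from the descriptor
#' comparison; group sizes are reported), one-way ANOVA with Tukey post
#' hoc and pairwise Welch t-tests, linear regressions of both descriptors
#' on OARSI grade, and the intraclass correlation of the replicate rater
#' columns. When a patient cohort table is supplied its descriptive
#' summary (mean age, range, mean of per-patient mean OARSI) is included;
#' the sample-level mean OARSI of the study table is reported alongside,
#' since averaging patients and averaging samples need not agree.
#'
#' @param table A study-table tibble (see [generate_study_table()] for the
#'   column contract); rater columns are those named `rater_*`.
#' @param cohort Optional patient cohort tibble (see [cohort_patients()]).
#' @param lbp_exclude_grade Bone grade excluded from descriptor group
#'   tests (default 3).
#' @return An object of class `study_report` (a named list); see
#'   [tidy.study_report()] for a flat view of the headline statistics.
#' @examples
#' tab <- generate_study_table(n_patients = 20, seed = 1)
#' rep <- reproduce_study(tab, cohort = cohort_patients())
#' rep$fold_change
#' @export
reproduce_study <- function(table, cohort = NULL, lbp_exclude_grade = 3) {
  validate_study_table(table)
  rater_cols <- grep("^rater_", names(table), value = TRUE)

  oarsi_by_grade <- summarize_by_grade(table, "oarsi")
  thickness_by_grade <- purrr::map_dfr(
    c(uncalcified_cartilage = "thickness_uncalc_um",
      calcified_cartilage = "thickness_calc_um",
      subchondral_plate = "thickness_plate_um"),
    function(col) summarize_by_grade(table, col),
    .id = "layer"
  )

  plate <- summarize_by_grade(table, "thickness_plate_um")
  fold <- NULL
  if (0 %in% plate$bone_grade) {
    ref <- plate$mean[plate$bone_grade == 0]
    others <- plate[plate$bone_grade != 0, ]
    if (nrow(others) > 0 && ref > 0) {
      fold <- dplyr::bind_cols(
        tibble::tibble(bone_grade = others$bone_grade),
        purrr::map_dfr(others$mean, ~ fold_change(ref, .x))
      )
    }
  }

  lbp_rows <- table[!is.na(table$entropy_bits) & !is.na(table$homogeneity), ]
  lbp_groups <- lbp_rows[lbp_rows$bone_grade != lbp_exclude_grade, ]
  group_sizes <- dplyr::count(lbp_groups, .data$bone_grade, name = "n")

  run_tests <- function(col) {
    vals <- lbp_groups[[col]]
    g <- lbp_groups$bone_grade
    if (length(unique(g)) < 2 || length(vals) <= length(unique(g))) {
      return(NULL)
    }
    pairs <- utils::combn(sort(unique(g)), 2, simplify = FALSE)
    t_tests <- purrr::map_dfr(pairs, function(p) {
      a <- vals[g == p[1]]
      b <- vals[g == p[2]]
      if (length(a) < 2 || length(b) < 2) {
        return(tibble::tibble(grade_a = p[1], grade_b = p[2],
                              t_statistic = NA_real_, df = NA_real_,
                              p_value = NA_real_,
                              mean_a = mean(a), mean_b = mean(b)))
      }
      dplyr::bind_cols(tibble::tibble(grade_a = p[1], grade_b = p[2]),
                       independent_t(a, b))
    })
    list(
      anova = one_way_anova(vals, g),
      tukey = tukey_hsd(vals, g),
      t_tests = t_tests
    )
  }

  regressions <- purrr::map(
    c(entropy_bits = "entropy_bits", homogeneity = "homogeneity"),
    function(col) {
      ok <- !is.na(lbp_rows[[col]])
      if (sum(ok) < 3) return(NULL)
      linear_regression(lbp_rows$oarsi[ok], lbp_rows[[col]][ok])
    }
  )

  icc <- NULL
  if (length(rater_cols) >= 2 && nrow(table) >= 2) {
    icc <- icc_consistency(as.matrix(table[rater_cols]))
  }

  structure(
    list(
      cohort_summary = if (!is.null(cohort)) summarize_cohort(cohort),
      sample_mean_oarsi = mean(table$oarsi),
      sample_sd_oarsi = stats::sd(table$oarsi),
      mean_bone_grade = mean(table$bone_grade),
      oarsi_by_grade = oarsi_by_grade,
      thickness_by_grade = thickness_by_grade,
      fold_change = fold,
      lbp_group_sizes = group_sizes,
      lbp_tests = list(entropy_bits = run_tests("entropy_bits"),
                       homogeneity = run_tests("homogeneity")),
      regressions = regressions,
      icc = icc,
      counts = tibble::tibble(
        n_samples = nrow(table),
        n_with_descriptors = nrow(lbp_rows),
        n_excluded_no_cartilage = nrow(table) - nrow(lbp_rows),
        n_descriptor_group_rows = nrow(lbp_groups)
      )
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("Grading study report\n")
  cat("====================\n")
  if (!is.null(x$cohort_summary)) {
    cs <- x$cohort_summary
    cat(sprintf("Cohort: %d patients, mean age %.1f (range %d-%d), mean OARSI %.2f\n",
                cs$n_patients, cs$mean_age, cs$age_min, cs$age_max,
                cs$mean_oarsi))
  }
  cat(sprintf("Samples: %d (mean OARSI %.2f, mean bone grade %.2f)\n",
              x$counts$n_samples, x$sample_mean_oarsi, x$mean_bone_grade))
  cat("\nMean OARSI by bone grade:\n")
  print(x$oarsi_by_grade)
  if (!is.null(x$fold_change)) {
    cat("\nSubchondral plate fold change vs grade 0:\n")
    print(x$fold_change)
  }
  if (!is.null(x$icc)) {
    cat(sprintf("\nRater consistency ICC = %.3f (%d samples x %d raters)\n",
                x$icc$icc, x$icc$n_samples, x$icc$n_raters))
  }
  for (d in names(x$regressions)) {
    r <- x$regressions[[d]]
    if (!is.null(r)) {
      cat(sprintf("Regression %s ~ OARSI: slope %.3f, R^2 = %.2f (n = %d)\n",
                  d, r$slope, r$r_squared, r$n))
    }
  }
  for (d in names(x$lbp_tests)) {
    t <- x$lbp_tests[[d]]
    if (!is.null(t)) {
      cat(sprintf("ANOVA %s across grades: F = %.2f, p = %.3g %s\n",
                  d, t$anova$f_statistic, t$anova$p_value,
                  signif_marks(t$anova$p_value)))
    }
  }
  cat(sprintf("\nDescriptor rows: %d of %d samples (%d lacked remaining cartilage)\n",
              x$counts$n_with_descriptors, x$counts$n_samples,
              x$counts$n_excluded_no_cartilage))
  invisible(x)
}

#' Flatten a study report to a tibble
#'
#' One row per headline statistic of a [reproduce_study()] report:
#' cohort summaries, per-grade OARSI means, plate fold changes, descriptor
#' regression slopes and R-squared, and the rater ICC.
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @return A tibble with columns `statistic` and `value`.
#' @export
tidy.study_report <- function(x, ...) {
  rows <- list()
  if (!is.null(x$cohort_summary)) {
    cs <- x$cohort_summary
    rows$cohort <- tibble::tibble(
      statistic = c("cohort_mean_age", "cohort_age_min", "cohort_age_max",
                    "cohort_mean_oarsi"),
      value = c(cs$mean_age, cs$age_min, cs$age_max, cs$mean_oarsi)
    )
  }
  rows$sample <- tibble::tibble(
    statistic = c("sample_mean_oarsi", "mean_bone_grade"),
    value = c(x$sample_mean_oarsi, x$mean_bone_grade)
  )
  rows$oarsi <- tibble::tibble(
    statistic = paste0("mean_oarsi_grade_", x$oarsi_by_grade$bone_grade),
    value = x$oarsi_by_grade$mean
  )
  if (!is.null(x$fold_change)) {
    rows$fold <- tibble::tibble(
      statistic = paste0("plate_fold_grade_", x$fold_change$bone_grade),
      value = x$fold_change$ratio
    )
  }
  for (d in names(x$regressions)) {
    r <- x$regressions[[d]]
    if (!is.null(r)) {
      rows[[paste0("reg_", d)]] <- tibble::tibble(
        statistic = paste0(c("slope_", "r_squared_"), d),
        value = c(r$slope, r$r_squared)
      )
    }
  }
  if (!is.null(x$icc)) {
    rows$icc <- tibble::tibble(statistic = "icc", value = x$icc$icc)
  }
  dplyr::bind_rows(rows)
}
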