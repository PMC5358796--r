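#' Default site-category to bone-grade mixing weights
#'
#' Probability of each subchondral bone grade (columns, grades 0--3) given
#' the harvesting-site category (rows): site 1 is the visually most intact
#' region of the tibial plateau and skews to low grades, site 3 is the
#' partly or fully exposed bone and skews high. The defaults are chosen so
#' the expected site-level mean OARSI (through the per-grade OARSI means of
#' [default_grade_profiles()]) approximates the observed site means of
#' about 2.1, 4.4 and 5.3.
#'
#' @return A 3 x 4 numeric matrix; rows sum to 1.
#' @export
default_site_grade_weights <- function() {
  w <- rbind(
    c(0.70, 0.20, 0.07, 0.03),
    c(0.00, 0.15, 0.50, 0.35),
    c(0.00, 0.05, 0.15, 0.80)
  )
  dimnames(w) <- list(paste0("site_", 1:3), paste0("grade_", 0:3))
  w
}

#' Generate a synthetic grading-study table
#'
#' Simulates the tabular output of an osteochondral grading study:
#' `n_patients` patients each contribute `samples_per_patient` samples
#' taken from site categories 1--3 (cycled in order). Each sample's true
#' subchondral bone grade is drawn from the site's mixing weights; its
#' OARSI cartilage grade, layer thicknesses and LBP interface descriptors
#' (entropy of local angles, ALCM homogeneity) are then drawn from that
#' grade's profile. Replicate rater scores are the true grade plus rounded
#' Gaussian noise with SD `rater_sd`, clipped to 0--3.
#'
#' Interface descriptors are reported only for samples with remaining
#' cartilage (OARSI below `oarsi_lbp_cutoff`); other rows carry `NA`, as
#' the LBP analysis is undefined once the cartilage layer is lost.
#'
#' @param n_patients Number of patients (>= 1).
#' @param samples_per_patient Samples per patient (>= 1); site categories
#'   1,2,3 repeat in order.
#' @param n_raters Number of replicate raters (>= 1).
#' @param rater_sd SD (grade units) of rater noise before rounding;
#'   0 makes all raters agree exactly with the true grade.
#' @param seed Integer seed; fixed seed gives a bit-identical table.
#' @param profiles Grade-profile tibble, default [default_grade_profiles()].
#' @param site_grade_weights 3 x 4 weight matrix, rows = site categories.
#' @param oarsi_lbp_cutoff OARSI grade at and above which interface
#'   descriptors are withheld (default 5).
#' @return A tibble with one row per sample: `sample_id`, `patient_id`,
#'   `site_category`, `oarsi`, `bone_grade`, `thickness_uncalc_um`,
#'   `thickness_calc_um`, `thickness_plate_um`, `entropy_bits`,
#'   `homogeneity`, `rater_1` ... `rater_<n_raters>`.
#' @examples
#' tab <- generate_study_table(n_patients = 20, seed = 1)
#' dplyr::count(tab, bone_grade)
#' @export
generate_study_table <- function(n_patients = 20, samples_per_patient = 3,
                                 n_raters = 3, rater_sd = 0.27, seed = 1,
                                 profiles = default_grade_profiles(),
                                 site_grade_weights = default_site_grade_weights(),
                                 oarsi_lbp_cutoff = 5) {
  stopifnot(n_patients >= 1, samples_per_patient >= 1, n_raters >= 1,
            rater_sd >= 0)
  validate_grade_profiles(profiles)
  if (!isTRUE(all.equal(rowSums(site_grade_weights), rep(1, 3),
                        check.attributes = FALSE))) {
    stop("site_grade_weights rows must sum to 1")
  }

  withr::with_seed(seed, {
    patient_id <- rep(seq_len(n_patients), each = samples_per_patient)
    sample_idx <- rep(seq_len(samples_per_patient), times = n_patients)
    site <- ((sample_idx - 1L) %% 3L) + 1L
    n <- length(patient_id)

    # restrict to the grades the profile table provides (weights are
    # renormalised row-wise over the available grades)
    grades_avail <- sort(profiles$grade)
    w <- site_grade_weights[, grades_avail + 1, drop = FALSE]
    if (any(rowSums(w) == 0)) {
      stop("site_grade_weights give no mass to any available grade")
    }
    w <- w / rowSums(w)
    grade <- integer(n)
    for (s in 1:3) {
      rows <- which(site == s)
      if (length(rows)) {
        grade[rows] <- sample(grades_avail, length(rows), replace = TRUE,
                              prob = w[s, ])
      }
    }
    k <- match(grade, profiles$grade)

    oarsi <- round(pmin(6, pmax(0, stats::rnorm(
      n, profiles$oarsi_mean[k], profiles$oarsi_sd[k]))), 1)
    thick <- function(mean, sd) clipped_normal(n, mean[k], sd[k])
    thickness_uncalc <- thick(profiles$uncalc_cart_mean, profiles$uncalc_cart_sd)
    thickness_calc <- thick(profiles$calc_cart_mean, profiles$calc_cart_sd)
    thickness_plate <- thick(profiles$plate_mean, profiles$plate_sd)

    entropy <- pmin(3, pmax(0, stats::rnorm(
      n, profiles$entropy_mean[k], profiles$entropy_sd[k])))
    homogeneity <- pmin(1, pmax(1e-6, stats::rnorm(
      n, profiles$homogeneity_mean[k], profiles$homogeneity_sd[k])))
    no_lbp <- oarsi >= oarsi_lbp_cutoff
    entropy[no_lbp] <- NA_real_
    homogeneity[no_lbp] <- NA_real_

    raters <- matrix(0L, n, n_raters)
    for (r in seq_len(n_raters)) {
      noise <- if (rater_sd > 0) stats::rnorm(n, 0, rater_sd) else 0
      raters[, r] <- as.integer(pmin(3, pmax(0, round(grade + noise))))
    }
    colnames(raters) <- paste0("rater_", seq_len(n_raters))

    out <- tibble::tibble(
      sample_id = sprintf("P%02d_S%d", patient_id, sample_idx),
      patient_id = patient_id,
      site_category = site,
      oarsi = oarsi,
      bone_grade = grade,
      thickness_uncalc_um = thickness_uncalc,
      thickness_calc_um = thickness_calc,
      thickness_plate_um = thickness_plate,
      entropy_bits = entropy,
      homogeneity = homogeneity
    )
    dplyr::bind_cols(out, tibble::as_tibble(raters))
  })
}

#' Validate a study table
#'
#' Checks range invariants of a grading-study table: OARSI in \[0, 6\],
#' bone grade in 0--3, non-negative thicknesses, and interface descriptors
#' present only for rows with OARSI below the LBP cutoff.
#'
#' @param table A study-table tibble.
#' @param oarsi_lbp_cutoff OARSI cutoff used when the table was built.
#' @return `table`, invisibly, if valid; otherwise an error.
#' @export
validate_study_table <- function(table, oarsi_lbp_cutoff = 5) {
  required <- c("sample_id", "patient_id", "site_category", "oarsi",
                "bone_grade", "thickness_uncalc_um", "thickness_calc_um",
                "thickness_plate_um", "entropy_bits", "homogeneity")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0) {
    stop("study table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (any(table$oarsi < 0 | table$oarsi > 6)) stop("oarsi out of [0, 6]")
  if (!all(table$bone_grade %in% 0:3)) stop("bone_grade out of 0..3")
  thick <- unlist(table[c("thickness_uncalc_um", "thickness_calc_um",
                          "thickness_plate_um")])
  if (any(thick < 0)) stop("thicknesses must be >= 0")
  high <- table$oarsi >= oarsi_lbp_cutoff
  if (any(!is.na(table$entropy_bits[high])) ||
      any(!is.na(table$homogeneity[high]))) {
    stop("interface descriptors must be NA for OARSI >= ", oarsi_lbp_cutoff)
  }
  invisible(table)
}
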