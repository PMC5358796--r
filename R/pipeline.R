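#' Pipeline configuration
#'
#' Bundles the tunable parameters of the end-to-end analysis. All lengths
#' are micrometres; the pixel size has no universal default in histology
#' (it depends on camera and magnification) and should be set to the
#' calibrated value of the acquisition -- the packaged default of 4 um/px
#' is the working resolution used for the synthetic studies.
#'
#' @param pixel_size Physical pixel size (um/px).
#' @param stain_channel Channel analysed for RGB inputs
#'   (`"red"` for Safranin-O).
#' @param band_half_width Chebyshev half-width of the BCI band (px);
#'   3 gives the nominal 7-px band.
#' @param angle_bins Number of local-angle bins.
#' @param oarsi_lbp_cutoff OARSI grade at and above which samples are
#'   excluded from the LBP analysis (no remaining cartilage).
#' @param noise_sd Intensity noise SD for simulated sections.
#' @param width_px,height_px Simulated raster size.
#' @param seed Root seed; all stage seeds are derived from it.
#' @param output_dir Optional directory for per-stage artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size = 4, stain_channel = "red",
                            band_half_width = 3, angle_bins = 8,
                            oarsi_lbp_cutoff = 5, noise_sd = 8,
                            width_px = 384, height_px = 384, seed = 1,
                            output_dir = NULL) {
  cfg <- list(
    pixel_size = pixel_size, stain_channel = stain_channel,
    band_half_width = band_half_width, angle_bins = angle_bins,
    oarsi_lbp_cutoff = oarsi_lbp_cutoff, noise_sd = noise_sd,
    width_px = width_px, height_px = height_px, seed = seed,
    output_dir = output_dir
  )
  numeric_fields <- c("pixel_size", "band_half_width", "angle_bins",
                      "oarsi_lbp_cutoff", "width_px", "height_px")
  for (f in numeric_fields) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop(f, " must be a positive number")
    }
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  class(cfg) <- "pipeline_config"
  cfg
}

# deterministic per-stage seeds derived from the root seed
derive_seeds <- function(root_seed, n) {
  withr::with_seed(root_seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Analyse one synthetic section end to end
#'
#' Convenience wrapper chaining phantom generation, band construction,
#' band classification, interface thinning, the local-angle descriptors
#' and the five-point thickness measurement for a single grade profile.
#'
#' @param profile One row of a grade-profile tibble.
#' @param config A [pipeline_config()].
#' @param seed Seed for this section.
#' @return A one-row tibble with the grade, seed, interface descriptors,
#'   per-layer mean thicknesses (um) and quality counts (undefined-angle
#'   fraction, border pixels dropped).
#' @export
analyze_section <- function(profile, config = pipeline_config(), seed = 1) {
  sec <- generate_section(
    profile, width_px = config$width_px, height_px = config$height_px,
    pixel_size = config$pixel_size, seed = seed, noise_sd = config$noise_sd
  )
  band <- band_from_layermap(sec$layers, half_width_px = config$band_half_width)
  labels <- classify_band(sec$image, band, method = "otsu")
  mask <- extract_interface(labels, band)
  field <- angle_field(sec$image, mask)
  desc <- describe_interface(sec$image, mask, n_bins = config$angle_bins)
  thick <- measure_section(sec, seed = seed)
  undef_frac <- mean(is.na(field$angle_deg))
  tibble::tibble(
    grade = profile$grade,
    seed = seed,
    entropy_bits = desc$entropy_bits,
    homogeneity = desc$homogeneity,
    n_defined_pixels = desc$n_defined_pixels,
    n_pairs = desc$n_pairs,
    thickness_uncalc_um = thick$mean_um[thick$layer == "uncalcified_cartilage"],
    thickness_calc_um = thick$mean_um[thick$layer == "calcified_cartilage"],
    thickness_plate_um = thick$mean_um[thick$layer == "subchondral_plate"],
    undefined_fraction = undef_frac,
    n_border_dropped = attr(field, "n_border_dropped")
  )
}

#' Run the full synthetic study pipeline
#'
#' Executes the whole analysis in the order simulate, segment, angles,
#' metrics, morphometry, statistics: renders `sections_per_grade` phantom
#' sections for each requested grade and reduces each to its interface
#' descriptors and layer thicknesses; simulates a grading-study table and
#' runs [reproduce_study()] on it (against the packaged patient cohort);
#' and logs every exclusion count (samples without remaining cartilage,
#' undefined-angle fractions, dropped border pixels) rather than dropping
#' anything silently. All randomness derives from `config$seed`, so
#' repeated runs with the same configuration are identical.
#'
#' @param config A [pipeline_config()].
#' @param grades Bone grades to simulate sections for (default 0--2, the
#'   grades whose interface is measurable).
#' @param sections_per_grade Phantom replicates per grade.
#' @param n_patients Patients in the simulated study table.
#' @param profiles Grade-profile tibble.
#' @param cohort Patient cohort used for the cohort summary block.
#' @return An object of class `pipeline_report`: list with `sections`
#'   (per-section tibble), `section_summary` (per-grade descriptor
#'   means), `study_table`, `study_report`, `log` and `config`. If
#'   `config$output_dir` is set, the study table (CSV), section summary
#'   (CSV) and tidied report (JSON) are also written there.
#' @export
run_pipeline <- function(config = pipeline_config(), grades = 0:2,
                         sections_per_grade = 5, n_patients = 20,
                         profiles = default_grade_profiles(),
                         cohort = cohort_patients()) {
  n_sections <- length(grades) * sections_per_grade
  seeds <- derive_seeds(config$seed, n_sections + 1)
  study_seed <- seeds[n_sections + 1]

  jobs <- tidyr::expand_grid(grade = grades,
                             replicate = seq_len(sections_per_grade))
  sections <- purrr::map_dfr(seq_len(nrow(jobs)), function(i) {
    prof <- profile_for_grade(profiles, jobs$grade[i])
    dplyr::bind_cols(
      tibble::tibble(replicate = jobs$replicate[i]),
      analyze_section(prof, config, seed = seeds[i])
    )
  })

  section_summary <- sections |>
    dplyr::group_by(.data$grade) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_entropy_bits = mean(.data$entropy_bits),
      mean_homogeneity = mean(.data$homogeneity),
      mean_thickness_plate_um = mean(.data$thickness_plate_um),
      .groups = "drop"
    )

  study_table <- generate_study_table(
    n_patients = n_patients, seed = study_seed,
    profiles = profiles, oarsi_lbp_cutoff = config$oarsi_lbp_cutoff
  )
  study_report <- reproduce_study(study_table, cohort = cohort)

  log <- tibble::tibble(
    n_sections = n_sections,
    mean_undefined_fraction = mean(sections$undefined_fraction),
    total_border_dropped = sum(sections$n_border_dropped),
    n_samples_excluded_no_cartilage =
      study_report$counts$n_excluded_no_cartilage
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_study_table(study_table,
                      file.path(config$output_dir, "study_table.csv"))
    readr::write_csv(section_summary,
                     file.path(config$output_dir, "section_summary.csv"))
    write_report(as.list(tidy(study_report)),
                 file.path(config$output_dir, "study_report.json"))
  }

  structure(
    list(sections = sections, section_summary = section_summary,
         study_table = study_table, study_report = study_report,
         log = log, config = config),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report:", x$log$n_sections, "sections,",
      nrow(x$study_table), "study samples\n")
  cat("\nPer-grade interface descriptors:\n")
  print(x$section_summary)
  cat("\n")
  print(x$study_report)
  invisible(x)
}
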