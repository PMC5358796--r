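#' Randomly selected but evenly distributed measurement columns
#'
#' Picks `k` measurement columns the way a histologist picks "randomly
#' selected but evenly distributed" points across one microscope view: the
#' image width is divided into `k` equal strips and one column is drawn
#' uniformly inside each strip.
#'
#' @param width_px Image width in pixels (>= `k`).
#' @param k Number of points (default 5).
#' @param seed Integer seed; fixed seed gives identical columns.
#' @return Integer vector of `k` column indices (1-based), one per strip,
#'   in left-to-right order.
#' @examples
#' sample_points(100, 5, seed = 1)  # point i falls in [20 (i - 1) + 1, 20 i]
#' @export
sample_points <- function(width_px, k = 5, seed = 1) {
  if (width_px < k) stop("width_px must be at least k")
  withr::with_seed(seed, {
    lo <- floor((seq_len(k) - 1) * width_px / k) + 1
    hi <- floor(seq_len(k) * width_px / k)
    vapply(seq_len(k), function(i) {
      if (lo[i] == hi[i]) lo[i] else sample(lo[i]:hi[i], 1)
    }, integer(1))
  })
}

#' Per-column layer thickness
#'
#' Vertical extent (chord length) of one layer at the given columns:
#' pixels carrying the layer's label are counted down each column and
#' converted to micrometres with the layer map's pixel size. A column in
#' which the layer is absent -- e.g. a plate column interrupted by an open
#' fenestra -- yields 0 um and is flagged rather than resampled, so the
#' caller can choose to exclude it.
#'
#' @param layers Integer layer-map matrix with a `pixel_size` attribute
#'   (um/px), as produced by [generate_section()].
#' @param columns Integer column indices inside the raster.
#' @param layer One of [layer_labels()].
#' @param pixel_size Override for the pixel size if `layers` carries none.
#' @return A tibble with one row per column: `layer`, `point`, `column`,
#'   `thickness_um`, `empty` (logical flag for zero-thickness columns).
#' @export
layer_thickness <- function(layers, columns, layer, pixel_size = NULL) {
  code <- layer_code(layer)
  if (any(columns < 1 | columns > ncol(layers))) {
    stop("columns must lie within the raster")
  }
  ps <- pixel_size %||% attr(layers, "pixel_size")
  if (is.null(ps)) stop("layer map carries no pixel_size; supply one")
  counts <- vapply(columns, function(j) sum(layers[, j] == code), numeric(1))
  tibble::tibble(
    layer = layer,
    point = seq_along(columns),
    column = as.integer(columns),
    thickness_um = counts * ps,
    empty = counts == 0
  )
}

#' Five-point thickness measurement of a section
#'
#' Measures uncalcified cartilage, calcified cartilage and subchondral
#' plate thickness of a (synthetic) section at `k` evenly distributed
#' random columns, shared across the three layers as in a single
#' microscope view, and reports the per-point values alongside their mean.
#'
#' @param section An `osteo_section` (or a bare layer-map matrix with a
#'   `pixel_size` attribute).
#' @param k Number of measurement points (default 5).
#' @param seed Seed for the column draw.
#' @param layers_to_measure Character vector of layer labels.
#' @return A tibble with one row per layer: `layer`, `p1` ... `p<k>`
#'   (um), `mean_um`, `n_empty` (number of zero-thickness points).
#' @export
measure_section <- function(section, k = 5, seed = 1,
                            layers_to_measure = c("uncalcified_cartilage",
                                                  "calcified_cartilage",
                                                  "subchondral_plate")) {
  layers <- if (inherits(section, "osteo_section")) section$layers else section
  cols <- sample_points(ncol(layers), k = k, seed = seed)
  purrr::map_dfr(layers_to_measure, function(lab) {
    pts <- layer_thickness(layers, cols, lab)
    wide <- stats::setNames(as.list(pts$thickness_um), paste0("p", seq_len(k)))
    tibble::tibble(
      layer = lab,
      !!!wide,
      mean_um = mean(pts$thickness_um),
      n_empty = sum(pts$empty)
    )
  })
}

#' Per-grade summary of a study measure
#'
#' Groups a study table by subchondral bone grade and reports the sample
#' size, mean, SD and standard error of one measure, the form in which
#' per-grade thickness and OARSI results are reported (mean +/- SE).
#' Grades absent from the table are omitted with a message; a grade with a
#' single row reports `NA` for SD and SE.
#'
#' @param table A study-table tibble with a `bone_grade` column.
#' @param measure Name of the numeric column to summarise (string).
#' @return A tibble with columns `bone_grade`, `n`, `mean`, `sd`, `se`.
#' @examples
#' tab <- generate_study_table(n_patients = 10, seed = 1)
#' summarize_by_grade(tab, "thickness_plate_um")
#' @export
summarize_by_grade <- function(table, measure) {
  if (!measure %in% names(table)) stop("no column called ", measure)
  x <- rlang::sym(measure)
  out <- table |>
    dplyr::filter(!is.na(!!x)) |>
    dplyr::group_by(.data$bone_grade) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(!!x),
      sd = ifelse(dplyr::n() > 1, stats::sd(!!x), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(se = .data$sd / sqrt(.data$n)) |>
    dplyr::arrange(.data$bone_grade)
  absent <- setdiff(0:3, out$bone_grade)
  if (length(absent) > 0) {
    message("no rows for grade(s) ", paste(absent, collapse = ", "),
            "; omitted from the summary")
  }
  out
}

#' Fold change of a grade mean against a reference grade
#'
#' Ratio of a grade's mean to the reference (grade 0) mean, also rounded
#' to the nearest integer fold as such changes are usually quoted (e.g. a
#' 3-fold plate thickening at grade 1).
#'
#' @param reference_mean Reference mean (> 0).
#' @param grade_mean Mean to compare.
#' @return A one-row tibble with columns `ratio` and `fold` (rounded).
#' @examples
#' fold_change(58, 176)  # ratio 3.03..., 3-fold
#' @export
fold_change <- function(reference_mean, grade_mean) {
  if (!is.finite(reference_mean) || reference_mean <= 0) {
    stop("reference_mean must be positive")
  }
  ratio <- grade_mean / reference_mean
  tibble::tibble(ratio = ratio, fold = round(ratio))
}
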