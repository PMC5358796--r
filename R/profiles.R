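#' Default subchondral bone grade profiles
#'
#' One row per subchondral bone grade (0--3) holding the simulation
#' parameters that characterise each stage of osteoarthritic change:
#' layer-thickness means and SDs (um), bone--cartilage interface (BCI)
#' roughness, the expected rate of open fenestrae in the subchondral plate,
#' the OARSI cartilage grade distribution observed at that bone grade, and
#' the generator means for the two LBP interface descriptors.
#'
#' Thickness and OARSI parameters follow the per-grade study values:
#' uncalcified cartilage 2374/1753/1826/82 um (SD 506/615/1268/142),
#' calcified cartilage 84/104/128/36 um (SD 69/62/50/46), subchondral plate
#' 58/176/473/1245 um (SD 28/87/229/448), mean OARSI 1.46/3.45/3.99/5.19.
#' Interface roughness amplitude rises from grade 0 to grade 2 (progressive
#' fibrillation of the plate surface) and drops again at grade 3, whose
#' plate is worn smooth. Open fenestrae connecting marrow to cartilage
#' occur only at grades 0--1.
#'
#' @param roughness_wavelengths Wavelengths (um) of the sinusoidal roughness
#'   components shared by all grades.
#' @return A tibble with 4 rows and columns `grade`, `uncalc_cart_mean`,
#'   `uncalc_cart_sd`, `calc_cart_mean`, `calc_cart_sd`, `plate_mean`,
#'   `plate_sd`, `roughness_amplitude`, `roughness_wavelengths`
#'   (list-column), `fenestra_rate` (expected open plate gaps per mm),
#'   `oarsi_mean`, `oarsi_sd`, `entropy_mean`, `entropy_sd`,
#'   `homogeneity_mean`, `homogeneity_sd`, `trabecular_fraction`.
#' @examples
#' default_grade_profiles()
#' @export
default_grade_profiles <- function(roughness_wavelengths = c(200, 100, 50)) {
  profiles <- tibble::tibble(
    grade = 0:3,
    uncalc_cart_mean = c(2374, 1753, 1826, 82),
    uncalc_cart_sd   = c(506, 615, 1268, 142),
    calc_cart_mean   = c(84, 104, 128, 36),
    calc_cart_sd     = c(69, 62, 50, 46),
    plate_mean       = c(58, 176, 473, 1245),
    plate_sd         = c(28, 87, 229, 448),
    roughness_amplitude = c(6, 14, 28, 4),
    roughness_wavelengths = rep(list(roughness_wavelengths), 4),
    fenestra_rate    = c(1.5, 0.8, 0, 0),
    oarsi_mean       = c(1.46, 3.45, 3.99, 5.19),
    oarsi_sd         = c(0.8, 0.8, 0.8, 0.6),
    entropy_mean     = c(1.30, 1.80, 2.20, 2.35),
    entropy_sd       = c(0.15, 0.15, 0.15, 0.15),
    homogeneity_mean = c(0.85, 0.72, 0.62, 0.58),
    homogeneity_sd   = c(0.03, 0.03, 0.03, 0.03),
    trabecular_fraction = c(0.25, 0.35, 0.50, 0.65)
  )
  validate_grade_profiles(profiles)
  profiles
}

#' Validate a grade-profile table
#'
#' Checks the structural invariants a profile table must satisfy before it
#' can drive the phantom generator: non-negative means and SDs, fenestrae
#' restricted to grades 0--1 (higher grades have no open connection between
#' marrow and cartilage), and OARSI parameters inside the 0--6 scale.
#'
#' @param profiles A tibble as returned by [default_grade_profiles()].
#' @return `profiles`, invisibly, if valid; otherwise an error.
#' @export
validate_grade_profiles <- function(profiles) {
  required <- c(
    "grade", "uncalc_cart_mean", "uncalc_cart_sd", "calc_cart_mean",
    "calc_cart_sd", "plate_mean", "plate_sd", "roughness_amplitude",
    "roughness_wavelengths", "fenestra_rate", "oarsi_mean", "oarsi_sd"
  )
  missing <- setdiff(required, names(profiles))
  if (length(missing) > 0) {
    stop("profile table is missing columns: ", paste(missing, collapse = ", "))
  }
  means <- unlist(profiles[c(
    "uncalc_cart_mean", "calc_cart_mean", "plate_mean"
  )])
  sds <- unlist(profiles[c("uncalc_cart_sd", "calc_cart_sd", "plate_sd")])
  if (any(means < 0)) stop("layer thickness means must be >= 0")
  if (any(sds < 0)) stop("layer thickness SDs must be >= 0")
  if (any(profiles$roughness_amplitude < 0)) {
    stop("roughness_amplitude must be >= 0")
  }
  if (any(profiles$fenestra_rate < 0)) stop("fenestra_rate must be >= 0")
  high <- profiles$grade >= 2
  if (any(profiles$fenestra_rate[high] > 0)) {
    stop("fenestra_rate must be 0 for grades 2 and 3")
  }
  if (any(profiles$oarsi_mean < 0 | profiles$oarsi_mean > 6)) {
    stop("oarsi_mean must lie in [0, 6]")
  }
  if (any(profiles$oarsi_sd < 0)) stop("oarsi_sd must be >= 0")
  invisible(profiles)
}

#' Look up the profile row for a single grade
#'
#' @param profiles A grade-profile tibble.
#' @param grade Integer grade in `profiles$grade`.
#' @return A one-row tibble.
#' @keywords internal
#' @noRd
profile_for_grade <- function(profiles, grade) {
  row <- profiles[profiles$grade == grade, ]
  if (nrow(row) != 1) {
    stop("no unique profile for grade ", grade)
  }
  row
}
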