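#' Layer labels used by the osteochondral phantom
#'
#' Fixed label set for the categorical layer map, in top-to-bottom
#' anatomical order: background above the articular surface, uncalcified
#' cartilage, calcified cartilage, subchondral plate, then trabecular bone
#' and marrow below the plate. Layer maps store the integer code
#' (1-based position in this vector).
#'
#' @return Character vector of the six layer labels.
#' @export
layer_labels <- function() {
  c("background", "uncalcified_cartilage", "calcified_cartilage",
    "subchondral_plate", "trabecular_bone", "marrow")
}

layer_code <- function(label) {
  code <- match(label, layer_labels())
  if (anyNA(code)) stop("unknown layer label: ", paste(label[is.na(code)], collapse = ", "))
  code
}

#' Sinusoidal interface roughness displacement
#'
#' Evaluates the boundary displacement model used by the phantom generator:
#' a sum of equal-amplitude sinusoids at the given wavelengths with the
#' given phases, scaled so that over many periods the column-wise standard
#' deviation of the displacement is `amplitude / sqrt(2)` (each component
#' has amplitude `amplitude / sqrt(n)`).
#'
#' @param x_um Horizontal positions (um) at which to evaluate.
#' @param amplitude Total roughness amplitude (um).
#' @param wavelengths Component wavelengths (um).
#' @param phases Component phases (radians), same length as `wavelengths`.
#' @return Numeric displacement (um) at each position.
#' @export
roughness_displacement <- function(x_um, amplitude, wavelengths, phases) {
  if (length(phases) != length(wavelengths)) {
    stop("phases and wavelengths must have the same length")
  }
  if (amplitude == 0 || length(wavelengths) == 0) {
    return(rep(0, length(x_um)))
  }
  a <- amplitude / sqrt(length(wavelengths))
  d <- rep(0, length(x_um))
  for (i in seq_along(wavelengths)) {
    d <- d + a * sin(2 * pi * x_um / wavelengths[i] + phases[i])
  }
  d
}

# thickness draw clipped to [max(0, mean - 3 sd), mean + 3 sd]
clipped_normal <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  pmin(mean + 3 * sd, pmax(pmax(0, mean - 3 * sd), x))
}

#' Default stain-channel intensities per layer
#'
#' Mean 8-bit intensity assigned to each layer in the analysed channel.
#' Bone (plate and trabeculae) is brighter than calcified cartilage, which
#' is brighter than uncalcified cartilage; marrow spaces are dark. Use the
#' `invert` argument of [generate_section()] for stains with the opposite
#' polarity.
#'
#' @return Named numeric vector over [layer_labels()].
#' @export
default_layer_intensities <- function() {
  c(background = 15, uncalcified_cartilage = 90, calcified_cartilage = 140,
    subchondral_plate = 200, trabecular_bone = 200, marrow = 60)
}

# smooth oriented noise field used to carve trabeculae out of the
# sub-plate region; wavelength in um
trabecular_field <- function(height_px, width_px, pixel_size,
                             wavelength_um = 150, n_components = 6) {
  f <- matrix(0, height_px, width_px)
  rr <- row(f) * pixel_size
  cc <- col(f) * pixel_size
  for (i in seq_len(n_components)) {
    theta <- stats::runif(1, 0, pi)
    lam <- wavelength_um * stats::runif(1, 0.6, 1.4)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + sin(2 * pi * (cos(theta) * cc + sin(theta) * rr) / lam + ph)
  }
  f
}

#' Generate a synthetic osteochondral section
#'
#' Renders a layered histology phantom for one subchondral bone grade:
#' horizontal layer baselines (uncalcified cartilage, calcified cartilage,
#' subchondral plate, trabecular bone/marrow) displaced by a random-phase
#' sum of sinusoids whose total amplitude is the profile's
#' `roughness_amplitude`. Layer thicknesses are drawn once per section from
#' the profile's mean and SD (clipped to mean +/- 3 SD and to zero below),
#' so column-to-column variation comes only from the roughness term. Open
#' fenestrae -- gaps in the plate connecting cartilage to the marrow space
#' -- are inserted at a Poisson rate per mm for profiles with
#' `fenestra_rate > 0`. Intensities follow
#' [default_layer_intensities()] plus additive Gaussian noise.
#'
#' The raster window is centred on the bone--cartilage interface, as in an
#' interface-level microscope view: the calcified cartilage and the plate
#' must fit inside the raster (otherwise the generator fails naming the
#' offending layer), while the uncalcified cartilage may run off the top
#' edge; any truncated layer is recorded in the returned object.
#'
#' The displacement field of the interface complex (cartilage/calcified
#' cartilage, calcified cartilage/plate, plate/trabecular boundaries) is
#' shared, so each layer's rendered thickness equals its drawn value in
#' every column; the articular surface gets an independent phase set.
#'
#' @param profile One-row tibble (a row of [default_grade_profiles()]).
#' @param width_px,height_px Raster size in pixels (both >= 64).
#' @param pixel_size Physical pixel size (um/px), > 0.
#' @param seed Integer seed; fixed seed gives a bit-identical section.
#' @param noise_sd SD of additive Gaussian intensity noise (8-bit units).
#' @param invert If `TRUE`, invert the intensity polarity (255 - I).
#' @param blur_sigma SD (px) of the Gaussian point-spread blur applied
#'   after the noise, emulating the band-limited optics of a microscope
#'   camera; 0 disables it. Without it the rendered texture would carry
#'   pixel-independent noise no real acquisition produces.
#' @param intensities Named intensity vector over [layer_labels()].
#' @param fenestra_width_um Range (um) from which fenestra widths are drawn.
#' @return An object of class `osteo_section`: a list with elements
#'   `image` (numeric matrix, 0--255), `layers` (integer matrix of layer
#'   codes with a `pixel_size` attribute), `pixel_size`, `boundaries`
#'   (per-column row positions of the articular surface, the
#'   cartilage/calcified-cartilage boundary, the BCI and the plate bottom),
#'   `thickness_um` (the drawn layer thicknesses), `truncated`, `grade`,
#'   `seed`.
#' @examples
#' prof <- default_grade_profiles()[1, ]
#' sec <- generate_section(prof, 128, 128, pixel_size = 8, seed = 1)
#' table(layer_labels()[sec$layers])
#' @export
generate_section <- function(profile, width_px = 512, height_px = 512,
                             pixel_size = 2, seed = 1, noise_sd = 8,
                             invert = FALSE, blur_sigma = 1,
                             intensities = default_layer_intensities(),
                             fenestra_width_um = c(30, 50)) {
  stopifnot(nrow(profile) == 1)
  if (width_px < 64 || height_px < 64) stop("raster must be at least 64x64")
  if (pixel_size <= 0) stop("pixel_size must be > 0")

  withr::with_seed(seed, {
    u_um <- clipped_normal(1, profile$uncalc_cart_mean, profile$uncalc_cart_sd)
    c_um <- clipped_normal(1, profile$calc_cart_mean, profile$calc_cart_sd)
    p_um <- clipped_normal(1, profile$plate_mean, profile$plate_sd)
    u_px <- round(u_um / pixel_size)
    c_px <- round(c_um / pixel_size)
    p_px <- round(p_um / pixel_size)
    # a section with remaining cartilage always shows some calcified
    # cartilage and plate; keep at least 2 px so the BCI exists
    if (profile$calc_cart_mean > 0) c_px <- max(c_px, 2)
    if (profile$plate_mean > 0) p_px <- max(p_px, 2)

    amp <- profile$roughness_amplitude
    wl <- profile$roughness_wavelengths[[1]]
    # max |displacement| of n equal sinusoids is amplitude * sqrt(n)
    amp_px <- ceiling(amp * sqrt(max(1, length(wl))) / pixel_size) + 1
    trab_min_px <- 8

    bci_row <- height_px - p_px - trab_min_px - amp_px
    if (bci_row - amp_px < 2) {
      stop("subchondral_plate does not fit in a ", height_px,
           "-px raster at ", pixel_size, " um/px (needs ",
           p_px + trab_min_px + 2 * amp_px + 2, " px)")
    }
    if (bci_row - amp_px - c_px < 1) {
      stop("calcified_cartilage does not fit in a ", height_px,
           "-px raster at ", pixel_size, " um/px")
    }

    x_um <- (seq_len(width_px) - 0.5) * pixel_size
    ph_bci <- stats::runif(length(wl), 0, 2 * pi)
    ph_surface <- stats::runif(length(wl), 0, 2 * pi)
    # continuous (sub-pixel) displacements drive the rendered intensities;
    # the label map uses their rounded version
    d_bci_f <- roughness_displacement(x_um, amp, wl, ph_bci) / pixel_size
    d_surf_f <- roughness_displacement(x_um, amp, wl, ph_surface) / pixel_size
    d_bci <- round(d_bci_f)
    d_surf <- round(d_surf_f)

    r_bci <- bci_row + d_bci                  # first plate row per column
    r_calc <- r_bci - c_px                    # first calcified-cartilage row
    r_plate_end <- r_bci + p_px - 1           # last plate row
    r_surf <- bci_row - c_px - u_px + d_surf  # first cartilage row
    truncated <- character(0)
    if (any(r_surf < 1)) truncated <- "uncalcified_cartilage"
    r_surf <- pmax(1, r_surf)
    # keep the anatomical order even for extreme surface displacements
    r_surf <- pmin(r_surf, r_calc)

    f_bci <- bci_row + d_bci_f
    f_calc <- f_bci - c_px
    f_surf <- pmin(pmax(1, bci_row - c_px - u_px + d_surf_f), f_calc)

    rows <- matrix(seq_len(height_px), height_px, width_px)
    surf_m <- matrix(r_surf, height_px, width_px, byrow = TRUE)
    calc_m <- matrix(r_calc, height_px, width_px, byrow = TRUE)
    bci_m <- matrix(r_bci, height_px, width_px, byrow = TRUE)
    pend_m <- matrix(r_plate_end, height_px, width_px, byrow = TRUE)

    layers <- matrix(layer_code("background"), height_px, width_px)
    layers[rows >= surf_m & rows < calc_m] <- layer_code("uncalcified_cartilage")
    layers[rows >= calc_m & rows < bci_m] <- layer_code("calcified_cartilage")
    layers[rows >= bci_m & rows <= pend_m] <- layer_code("subchondral_plate")

    below <- rows > pend_m
    if (any(below)) {
      f <- trabecular_field(height_px, width_px, pixel_size)
      thr <- stats::quantile(f[below], 1 - profile$trabecular_fraction)
      bone_below <- below & f >= thr
      layers[below] <- layer_code("marrow")
      layers[bone_below] <- layer_code("trabecular_bone")
    }

    fen_cols <- integer(0)
    if (profile$fenestra_rate > 0 && p_px > 0) {
      width_mm <- width_px * pixel_size / 1000
      n_fen <- stats::rpois(1, profile$fenestra_rate * width_mm)
      if (n_fen > 0) {
        centers <- sort(stats::runif(n_fen, 1, width_px))
        widths_px <- pmax(1, round(stats::runif(
          n_fen, fenestra_width_um[1], fenestra_width_um[2]) / pixel_size))
        for (i in seq_len(n_fen)) {
          cols <- max(1, round(centers[i] - widths_px[i] / 2)):
            min(width_px, round(centers[i] + widths_px[i] / 2))
          fen_cols <- union(fen_cols, cols)
          for (j in cols) {
            layers[r_bci[j]:r_plate_end[j], j] <- layer_code("marrow")
          }
        }
      }
    }

    # anti-aliased rendering: layer transitions at their continuous
    # positions with partial-volume blending, so the image carries the
    # sub-pixel boundary location a real acquisition would
    base <- intensities[layer_labels()]
    coverage <- function(fb) {
      fm <- matrix(fb, height_px, width_px, byrow = TRUE)
      pmax(pmin(rows - fm + 1, 1), 0)
    }
    image <- base["background"] +
      (base["uncalcified_cartilage"] - base["background"]) * coverage(f_surf) +
      (base["calcified_cartilage"] - base["uncalcified_cartilage"]) *
        coverage(f_calc) +
      (base["subchondral_plate"] - base["calcified_cartilage"]) *
        coverage(f_bci)
    below <- rows > pend_m
    image[below] <- base[layers[below]]
    for (j in fen_cols) {
      image[r_bci[j]:r_plate_end[j], j] <- base["marrow"]
    }
    if (noise_sd > 0) {
      image <- image + matrix(stats::rnorm(length(image), 0, noise_sd),
                              height_px, width_px)
    }
    image <- gaussian_blur(image, blur_sigma)
    image <- pmax(pmin(image, 255), 0)
    if (invert) image <- 255 - image

    attr(layers, "pixel_size") <- pixel_size
    structure(
      list(
        image = image,
        layers = layers,
        pixel_size = pixel_size,
        boundaries = list(
          cartilage_surface = r_surf,
          uncalc_calc = r_calc,
          bci = r_bci,
          plate_bottom = r_plate_end
        ),
        thickness_um = c(uncalcified_cartilage = u_um,
                         calcified_cartilage = c_um,
                         subchondral_plate = p_um),
        truncated = truncated,
        grade = profile$grade,
        seed = seed
      ),
      class = "osteo_section"
    )
  })
}

#' @export
print.osteo_section <- function(x, ...) {
  cat("<osteo_section> grade", x$grade, "--",
      nrow(x$image), "x", ncol(x$image), "px at",
      x$pixel_size, "um/px\n")
  cat("  drawn thickness (um):",
      paste(names(x$thickness_um), round(x$thickness_um), collapse = ", "),
      "\n")
  if (length(x$truncated)) {
    cat("  truncated at raster edge:", paste(x$truncated, collapse = ", "), "\n")
  }
  invisible(x)
}
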