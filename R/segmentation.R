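#' Otsu threshold of an intensity sample
#'
#' Maximises the between-class variance over a binned histogram of the
#' supplied intensities. Operates on a plain vector so it can be restricted
#' to the pixels of a band mask rather than a whole image.
#'
#' @param x Numeric intensities.
#' @param n_bins Number of histogram bins.
#' @return The threshold value; pixels `>= threshold` form the upper class.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) {
    stop("cannot threshold a constant-intensity region: no separable classes")
  }
  breaks <- seq(r[1], r[2], length.out = n_bins + 1)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  h <- tabulate(bin, n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  breaks[k + 1]
}

#' Classify band pixels as cartilage or bone
#'
#' Labels every pixel of a thick interface band as cartilage or bone by
#' intensity thresholding. With `method = "otsu"` the threshold is computed
#' from the band pixels only, so surrounding tissue does not bias the
#' split; with `method = "fixed"` a threshold must be supplied. By default
#' bone is the brighter class in the analysed channel (see
#' [default_layer_intensities()]); set `bone_brighter = FALSE` for inverted
#' stains.
#'
#' @param image Numeric intensity matrix.
#' @param band Logical band-mask matrix of the same size with at least
#'   9 `TRUE` pixels.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param threshold Threshold intensity, required for `method = "fixed"`.
#' @param bone_brighter If `TRUE`, intensities at or above the threshold
#'   are bone.
#' @return An integer matrix of the same size: `NA` outside the band,
#'   1 = cartilage, 2 = bone, with attributes `threshold` and `levels`.
#' @export
classify_band <- function(image, band, method = c("otsu", "fixed"),
                          threshold = NULL, bone_brighter = TRUE) {
  method <- match.arg(method)
  check_same_dim(image, band, "image", "band")
  if (sum(band) < 9) stop("band must contain at least 9 pixels")
  vals <- image[band]
  thr <- switch(method,
    otsu = otsu_threshold(vals),
    fixed = {
      if (is.null(threshold)) stop("method = \"fixed\" requires a threshold")
      threshold
    }
  )
  labels <- matrix(NA_integer_, nrow(image), ncol(image))
  upper <- image >= thr
  if (bone_brighter) {
    labels[band] <- ifelse(upper[band], 2L, 1L)
  } else {
    labels[band] <- ifelse(upper[band], 1L, 2L)
  }
  attr(labels, "threshold") <- thr
  attr(labels, "levels") <- c("cartilage", "bone")
  labels
}

#' Thin a classified band to the interface mask
#'
#' Keeps a band pixel if and only if its 8-neighbourhood, restricted to the
#' band, contains at least one pixel of the opposite class. On a smooth
#' class boundary this retains the two one-pixel boundary layers plus
#' pixels touching both, giving the roughly three-pixel-thick interface
#' mask the local-angle analysis runs on.
#'
#' @param labels Integer label matrix from [classify_band()] (`NA` outside
#'   the band).
#' @param band Logical band-mask matrix.
#' @return Logical interface-mask matrix (always a subset of `band`). If
#'   the band contains a single class the mask is empty and a warning is
#'   raised.
#' @export
extract_interface <- function(labels, band) {
  check_same_dim(labels, band, "labels", "band")
  labels[!band] <- NA_integer_
  keep <- matrix(FALSE, nrow(labels), ncol(labels))
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- shift_matrix(labels, dr, dc)
      opp <- !is.na(labels) & !is.na(nb) & labels != nb
      keep <- keep | opp
    }
  }
  keep <- keep & band
  if (!any(keep)) {
    warning("band contains a single class; returning an empty interface mask")
  }
  keep
}

#' Build a band mask around the BCI of a synthetic layer map
#'
#' Stands in for the manual band drawing of real sections: locates the
#' calcified-cartilage/subchondral-plate boundary of a layer map (the
#' topmost plate pixel of each column) and dilates it by the Chebyshev
#' distance `half_width_px`, giving a `2 * half_width_px + 1` pixel band on
#' flat boundaries (7 px at the default). The immediate cartilage-side
#' neighbour of each boundary pixel is always included so both classes are
#' represented even at `half_width_px = 0`. Columns without plate (open
#' fenestrae) contribute no boundary pixel of their own.
#'
#' @param layers Integer layer-map matrix (codes into [layer_labels()]).
#' @param half_width_px Chebyshev dilation radius in pixels (default 3).
#' @return Logical band-mask matrix with attribute `nominal_thickness_px`.
#' @export
band_from_layermap <- function(layers, half_width_px = 3) {
  stopifnot(half_width_px >= 0)
  for (lab in c("calcified_cartilage", "subchondral_plate")) {
    if (!any(layers == layer_code(lab))) {
      stop("layer map contains no ", lab, " pixels; BCI boundary is absent")
    }
  }
  h <- nrow(layers)
  w <- ncol(layers)
  plate <- layers == layer_code("subchondral_plate")
  boundary <- matrix(FALSE, h, w)
  top_plate <- apply(plate, 2, function(col) {
    i <- which(col)
    if (length(i) == 0) NA_integer_ else min(i)
  })
  has <- !is.na(top_plate)
  boundary[cbind(top_plate[has], which(has))] <- TRUE

  band <- matrix(FALSE, h, w)
  for (dr in -half_width_px:half_width_px) {
    for (dc in -half_width_px:half_width_px) {
      band <- band | shift_matrix(boundary, dr, dc, fill = FALSE)
    }
  }
  above <- cbind(pmax(1, top_plate[has] - 1), which(has))
  band[above] <- TRUE
  # columns with no plate (open fenestrae) hold no bone-cartilage
  # interface, and the columns flanking a gap mostly cover the fenestra
  # wall (a plate-marrow face): a manual operator skips both, so the
  # synthetic band drops the gap plus a half-width margin around it
  if (any(!has)) {
    gap <- !has
    skip <- gap
    if (half_width_px > 0) {
      for (dc in seq_len(half_width_px)) {
        skip <- skip | c(gap[-seq_len(dc)], rep(FALSE, dc)) |
          c(rep(FALSE, dc), gap[seq_len(w - dc)])
      }
    }
    band[, skip] <- FALSE
  }
  attr(band, "nominal_thickness_px") <- 2 * half_width_px + 1
  band
}
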