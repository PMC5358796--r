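# Compass neighbour layout at radius 1, counter-clockwise from East, with
# the raster convention row 1 = top (so North is row - 1). theta is the
# compass direction in degrees; cos2/sin2 are the exact doubled-angle unit
# vector components used for axial averaging.
lbp_offsets <- function() {
  data.frame(
    name = c("E", "NE", "N", "NW", "W", "SW", "S", "SE"),
    dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
    dc = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L),
    theta = c(0, 45, 90, 135, 180, 225, 270, 315),
    cos2 = c(1, 0, -1, 0, 1, 0, -1, 0),
    sin2 = c(0, 1, 0, -1, 0, 1, 0, -1)
  )
}

#' Local binary pattern at one pixel
#'
#' Compares the 8 radius-1 neighbours of a pixel against the pixel itself:
#' a flag is set when the neighbour's grey level is equal to or higher than
#' the centre (ties count as set). Flags are ordered E, NE, N, NW, W, SW,
#' S, SE, counter-clockwise from East with North pointing up the raster.
#'
#' @param image Numeric intensity matrix.
#' @param row,col Pixel position; all 8 neighbours must lie inside the
#'   raster (border pixels are excluded upstream by [angle_field()]).
#' @return Named integer vector of 8 flags (0/1).
#' @examples
#' img <- matrix(1, 3, 3)
#' local_pattern(img, 2, 2)  # constant image: all ties, all flags set
#' @export
local_pattern <- function(image, row, col) {
  if (row <= 1 || row >= nrow(image) || col <= 1 || col >= ncol(image)) {
    stop("pixel (", row, ", ", col, ") is on the raster border; ",
         "all 8 neighbours must exist")
  }
  offs <- lbp_offsets()
  centre <- image[row, col]
  flags <- integer(8)
  for (k in 1:8) {
    flags[k] <- as.integer(image[row + offs$dr[k], col + offs$dc[k]] >= centre)
  }
  names(flags) <- offs$name
  flags
}

#' Local orientation of a binary pattern
#'
#' Maps an 8-flag local binary pattern to an axial orientation in
#' \[0, 180) degrees by the angle-doubling construction: each set flag
#' contributes the unit vector (cos 2\eqn{\theta}, sin 2\eqn{\theta}) of
#' its compass direction, the contributions are summed, and half the
#' resultant's direction (mod 180) is returned. Doubling makes opposite
#' neighbours (e.g. E and W) reinforce rather than cancel, as an interface
#' orientation has no sign. The orientation is undefined -- `NA` -- when
#' all flags are set, no flag is set, or the doubled resultant's magnitude
#' falls below `eps`.
#'
#' @param pattern Integer/logical vector of 8 flags in E, NE, N, NW, W,
#'   SW, S, SE order (as from [local_pattern()]).
#' @param eps Magnitude below which the resultant is treated as undefined.
#' @return Angle in degrees in \[0, 180), or `NA_real_`.
#' @examples
#' pattern_to_angle(c(1, 0, 0, 0, 1, 0, 0, 0))  # E + W -> 0 (horizontal)
#' pattern_to_angle(c(0, 0, 1, 0, 0, 0, 1, 0))  # N + S -> 90
#' @export
pattern_to_angle <- function(pattern, eps = 1e-9) {
  pattern <- as.integer(as.logical(pattern))
  if (length(pattern) != 8 || anyNA(pattern)) {
    stop("pattern must be 8 binary flags")
  }
  s <- sum(pattern)
  if (s == 0 || s == 8) return(NA_real_)
  offs <- lbp_offsets()
  x <- sum(pattern * offs$cos2)
  y <- sum(pattern * offs$sin2)
  if (sqrt(x^2 + y^2) < eps) return(NA_real_)
  (atan2(y, x) * 90 / pi) %% 180
}

#' Exhaustive pattern-to-angle lookup table
#'
#' Enumerates all 256 local binary patterns with the orientation each maps
#' to, so the angle assignment is fully auditable. Patterns are indexed by
#' the byte `sum(flag_k * 2^(k-1))` over the E, NE, N, NW, W, SW, S, SE
#' flag order.
#'
#' @return A tibble with columns `code` (0--255), the 8 flag columns, and
#'   `angle_deg` (`NA` where the orientation is undefined).
#' @export
lbp_angle_table <- function() {
  codes <- 0:255
  flags <- t(vapply(codes, function(code) {
    as.integer(intToBits(code)[1:8])
  }, integer(8)))
  colnames(flags) <- lbp_offsets()$name
  angle <- apply(flags, 1, pattern_to_angle)
  dplyr::bind_cols(tibble::tibble(code = codes),
                   tibble::as_tibble(flags),
                   tibble::tibble(angle_deg = angle))
}

#' Per-pixel local angles over an interface mask
#'
#' Computes the LBP orientation of every interface-mask pixel. Mask pixels
#' on the raster border lack a full neighbourhood and are dropped; their
#' count is recorded in the `n_border_dropped` attribute. Undefined
#' orientations are kept as `NA` rows (they are a value, not an error).
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical interface-mask matrix of the same size, non-empty.
#' @param eps Passed to the orientation resultant test.
#' @return A tibble of class `angle_field` with columns `row`, `col`,
#'   `angle_deg`, and attributes `n_border_dropped` and `dim`.
#' @export
angle_field <- function(image, mask, eps = 1e-9) {
  check_same_dim(image, mask, "image", "mask")
  if (!any(mask)) stop("interface mask is empty")
  h <- nrow(image)
  w <- ncol(image)
  border <- matrix(FALSE, h, w)
  border[c(1, h), ] <- TRUE
  border[, c(1, w)] <- TRUE
  dropped <- sum(mask & border)
  use <- mask & !border
  if (!any(use)) stop("all mask pixels lie on the raster border")

  offs <- lbp_offsets()
  x <- matrix(0, h, w)
  y <- matrix(0, h, w)
  s <- matrix(0L, h, w)
  for (k in 1:8) {
    nb <- shift_matrix(image, offs$dr[k], offs$dc[k])
    f <- !is.na(nb) & nb >= image
    s <- s + f
    x <- x + f * offs$cos2[k]
    y <- y + f * offs$sin2[k]
  }
  angle <- (atan2(y, x) * 90 / pi) %% 180
  undef <- s == 0L | s == 8L | sqrt(x^2 + y^2) < eps
  angle[undef] <- NA_real_

  idx <- which(use)
  pos <- arrayInd(idx, c(h, w))
  out <- tibble::tibble(
    row = pos[, 1],
    col = pos[, 2],
    angle_deg = angle[idx]
  )
  attr(out, "n_border_dropped") <- dropped
  attr(out, "raster_dim") <- c(h, w)
  class(out) <- c("angle_field", class(out))
  out
}

#' Bin an angle field into an angle histogram
#'
#' Tallies the defined angles of an angle field into `n_bins` uniform
#' half-open bins over \[0, 180) and normalises by the defined-pixel
#' count.
#'
#' @param field An `angle_field` tibble (or any tibble with `angle_deg`).
#' @param n_bins Number of bins (default 8, i.e. 22.5 degree width).
#' @return A tibble of class `angle_histogram` with columns `bin`,
#'   `lower_deg`, `upper_deg`, `probability`, and attributes `n_defined`
#'   and `n_undefined`.
#' @export
angle_histogram <- function(field, n_bins = 8) {
  stopifnot(n_bins >= 1)
  angles <- field$angle_deg
  defined <- angles[!is.na(angles)]
  n_undef <- sum(is.na(angles))
  if (length(defined) == 0) {
    stop("no defined angles to bin (", n_undef, " undefined pixels)")
  }
  width <- 180 / n_bins
  bin <- pmin(n_bins, floor(defined / width) + 1L)
  counts <- tabulate(bin, n_bins)
  out <- tibble::tibble(
    bin = seq_len(n_bins),
    lower_deg = (seq_len(n_bins) - 1) * width,
    upper_deg = seq_len(n_bins) * width,
    probability = counts / length(defined)
  )
  attr(out, "n_defined") <- length(defined)
  attr(out, "n_undefined") <- n_undef
  class(out) <- c("angle_histogram", class(out))
  out
}
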