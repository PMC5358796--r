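#' Shannon entropy of an angle histogram
#'
#' Entropy of the local-angle distribution, the disorder ("fibrillation")
#' index of the bone--cartilage interface: `-sum(p * log(p))` with the
#' convention `0 * log(0) = 0`. A flat interface concentrates all mass in
#' one bin (entropy 0); a fully disordered one approaches `log2(n_bins)`
#' bits.
#'
#' @param h An `angle_histogram` tibble or a numeric probability vector.
#' @param base Logarithm base; 2 (default) reports bits.
#' @return Entropy (non-negative scalar).
#' @examples
#' angle_entropy(rep(1 / 8, 8))  # 3 bits
#' @export
angle_entropy <- function(h, base = 2) {
  p <- if (is.data.frame(h)) h$probability else as.numeric(h)
  if (any(p < 0)) stop("probabilities must be >= 0")
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1")
  nz <- p[p > 0]
  -sum(nz * log(nz, base = base))
}

#' Angle-level co-occurrence matrix (ALCM)
#'
#' Co-occurrence of binned local angles between 8-adjacent pairs of
#' defined interface pixels. Every unordered adjacent pair increments both
#' `(bin_a, bin_b)` and `(bin_b, bin_a)`, and all 8 adjacency directions
#' are pooled into one matrix -- the 2D rotation-invariant reading of the
#' co-occurrence construction -- before normalising to total mass 1.
#'
#' @param field An `angle_field` tibble (needs `row`, `col`, `angle_deg`
#'   and a `dim` attribute, as returned by [angle_field()]).
#' @param n_bins Number of angle bins (default 8).
#' @return An `n_bins` x `n_bins` symmetric probability matrix of class
#'   `alcm` with attribute `n_pairs` (number of unordered pairs counted).
#' @export
alcm <- function(field, n_bins = 8) {
  dims <- attr(field, "raster_dim")
  if (is.null(dims)) {
    dims <- c(max(field$row) + 1, max(field$col) + 1)
  }
  width <- 180 / n_bins
  bins <- matrix(NA_integer_, dims[1], dims[2])
  defined <- !is.na(field$angle_deg)
  bins[cbind(field$row[defined], field$col[defined])] <-
    pmin(n_bins, floor(field$angle_deg[defined] / width) + 1L)

  counts <- matrix(0, n_bins, n_bins)
  # E, SE, S, SW offsets cover each unordered 8-adjacent pair exactly once
  for (k in list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))) {
    nb <- shift_matrix(bins, k[1], k[2])
    ok <- !is.na(bins) & !is.na(nb)
    if (any(ok)) {
      tab <- table(factor(bins[ok], levels = seq_len(n_bins)),
                   factor(nb[ok], levels = seq_len(n_bins)))
      counts <- counts + unclass(tab)
    }
  }
  n_pairs <- sum(counts)
  if (n_pairs == 0) {
    stop("no 8-adjacent pairs of defined-angle pixels; ALCM is undefined")
  }
  m <- (counts + t(counts)) / (2 * n_pairs)
  dimnames(m) <- NULL
  attr(m, "n_pairs") <- n_pairs
  class(m) <- c("alcm", class(m))
  m
}

#' Homogeneity of an ALCM
#'
#' The co-occurrence homogeneity index `sum(P(i, j) / (1 + d(i, j)))` with
#' bin distance `d = |i - j|` (or the circular distance
#' `min(|i - j|, n - |i - j|)` when `circular = TRUE`). It equals 1 when
#' every adjacent interface pixel pair shares an angle bin -- a smooth,
#' continuous interface -- and decreases as sharp angle changes between
#' consecutive pixels become common.
#'
#' @param m An `alcm` matrix (entries >= 0 summing to 1).
#' @param circular If `TRUE`, measure bin distance around the 180-degree
#'   wrap instead of linearly.
#' @return Homogeneity in (0, 1].
#' @examples
#' alcm_homogeneity(matrix(c(0, .5, .5, 0), 2))  # 0.5
#' @export
alcm_homogeneity <- function(m, circular = FALSE) {
  m <- unclass(m)
  if (any(m < 0) || abs(sum(m) - 1) > 1e-8) {
    stop("ALCM entries must be >= 0 and sum to 1")
  }
  n <- nrow(m)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  if (circular) d <- pmin(d, n - d)
  sum(m / (1 + d))
}

#' Interface descriptors: entropy and homogeneity of local angles
#'
#' Runs the full local-angle analysis on one section: computes the angle
#' field over the interface mask, bins it, and reduces it to the two
#' scalar BCI descriptors -- Shannon entropy of the angle distribution
#' (bits) and ALCM homogeneity -- together with the pixel and pair counts
#' the estimates rest on. Samples without remaining cartilage (OARSI >= 5)
#' should be excluded before calling: the interface is not measurable
#' there.
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical interface-mask matrix.
#' @param n_bins Number of angle bins (default 8).
#' @param circular Passed to [alcm_homogeneity()].
#' @return A one-row tibble with columns `entropy_bits`, `homogeneity`,
#'   `n_defined_pixels`, `n_pairs`, `n_bins`.
#' @export
describe_interface <- function(image, mask, n_bins = 8, circular = FALSE) {
  field <- angle_field(image, mask)
  hist <- angle_histogram(field, n_bins = n_bins)
  m <- alcm(field, n_bins = n_bins)
  tibble::tibble(
    entropy_bits = angle_entropy(hist, base = 2),
    homogeneity = alcm_homogeneity(m, circular = circular),
    n_defined_pixels = attr(hist, "n_defined"),
    n_pairs = as.numeric(attr(m, "n_pairs")),
    n_bins = n_bins
  )
}
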