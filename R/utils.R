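# Shift a matrix by (dr, dc) so that out[r, c] = m[r + dr, c + dc],
# filling positions that fall outside the raster with `fill`.
shift_matrix <- function(m, dr, dc, fill = NA) {
  h <- nrow(m)
  w <- ncol(m)
  out <- matrix(fill, h, w)
  r_dst <- max(1, 1 - dr):min(h, h - dr)
  c_dst <- max(1, 1 - dc):min(w, w - dc)
  if (length(r_dst) > 0 && length(c_dst) > 0) {
    out[r_dst, c_dst] <- m[r_dst + dr, c_dst + dc]
  }
  out
}

# Separable Gaussian convolution with edge replication; sigma in pixels.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  radius <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-radius:radius, sd = sigma)
  k <- k / sum(k)
  pad_idx <- function(n) c(rep(1L, radius), seq_len(n), rep(n, radius))
  conv_cols <- function(x) {
    xp <- x[pad_idx(nrow(x)), , drop = FALSE]
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(k)) {
      out <- out + k[i] * xp[i:(i + nrow(x) - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(m))))
}

check_same_dim <- function(a, b, what_a, what_b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop(what_a, " and ", what_b, " must have the same dimensions")
  }
  invisible(TRUE)
}
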