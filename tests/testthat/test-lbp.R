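test_that("local patterns follow the equal-or-higher tie rule", {
  expect_equal(unname(local_pattern(matrix(5, 3, 3), 2, 2)), rep(1L, 8))
  img <- matrix(1, 3, 3)
  img[2, 2] <- 9
  expect_equal(unname(local_pattern(img, 2, 2)), rep(0L, 8))
  # vertical ramp, brighter upward: the level set (E, W) ties as set
  ramp <- matrix(rep(c(30, 20, 10), each = 1), 3, 3, byrow = FALSE)
  p <- local_pattern(ramp, 2, 2)
  expect_equal(p[c("N", "NE", "NW", "E", "W")], c(N = 1L, NE = 1L, NW = 1L,
                                                  E = 1L, W = 1L))
  expect_equal(p[c("S", "SE", "SW")], c(S = 0L, SE = 0L, SW = 0L))
  expect_error(local_pattern(img, 1, 2), "border")
})

test_that("axial symmetry pairs map to their shared orientation", {
  flag <- function(...) {
    f <- integer(8)
    names(f) <- c("E", "NE", "N", "NW", "W", "SW", "S", "SE")
    f[c(...)] <- 1L
    f
  }
  expect_equal(pattern_to_angle(flag("E", "W")), 0)
  expect_equal(pattern_to_angle(flag("N", "S")), 90)
  expect_equal(pattern_to_angle(flag("NE", "SW")), 45)
  expect_equal(pattern_to_angle(flag("NW", "SE")), 135)
  expect_true(is.na(pattern_to_angle(rep(1, 8))))
  expect_true(is.na(pattern_to_angle(rep(0, 8))))
  # opposite quadrant pairs cancel in the doubled space
  expect_true(is.na(pattern_to_angle(flag("NE", "NW"))))
})

test_that("all 256 patterns match the brute-force axial-mean oracle", {
  tab <- lbp_angle_table()
  expect_equal(nrow(tab), 256)
  flags <- as.matrix(tab[, c("E", "NE", "N", "NW", "W", "SW", "S", "SE")])
  oracle <- apply(flags, 1, oracle_axial_mean)
  expect_identical(is.na(tab$angle_deg), is.na(oracle))
  ok <- !is.na(oracle)
  expect_equal(tab$angle_deg[ok], oracle[ok], tolerance = 1e-9)
  # codes re-encode their own flag rows
  expect_equal(tab$code, as.integer(flags %*% 2^(0:7)))
})

test_that("angle fields recover flat and diagonal interface orientations", {
  img <- step_image(20, 10)
  band <- matrix(FALSE, 20, 20)
  band[7:14, ] <- TRUE
  mask <- extract_interface(
    classify_band(img, band, method = "fixed", threshold = 150), band)
  f <- angle_field(img, mask)
  expect_true(all(f$angle_deg[!is.na(f$angle_deg)] == 0))

  img45 <- outer(1:24, 1:24, function(i, j) ifelse(i + j >= 26, 200, 100))
  band45 <- abs(outer(1:24, 1:24, "+") - 25.5) <= 3.5
  mask45 <- extract_interface(
    classify_band(img45, band45, method = "fixed", threshold = 150), band45)
  f45 <- angle_field(img45, mask45)
  defined <- f45$angle_deg[!is.na(f45$angle_deg)]
  expect_gt(length(defined), 0)
  expect_true(all(abs(defined - 45) <= 22.5))
})

test_that("constant images yield only undefined orientations", {
  img <- matrix(3, 10, 10)
  mask <- matrix(FALSE, 10, 10)
  mask[4:6, 4:6] <- TRUE
  f <- angle_field(img, mask)
  expect_true(all(is.na(f$angle_deg)))
  expect_error(angle_histogram(f), "undefined")
})

test_that("angle fields are invariant to intensity shifts and covariant to rotation", {
  withr::with_seed(31, img <- matrix(stats::runif(400, 0, 255), 20, 20))
  mask <- matrix(FALSE, 20, 20)
  mask[5:16, 5:16] <- TRUE
  f1 <- angle_field(img, mask)
  f2 <- angle_field(img + 40, mask)
  expect_identical(f1$angle_deg, f2$angle_deg)

  # clockwise quarter turn: (r, c) -> (c, H + 1 - r); axial angles + 90 deg
  rot <- function(m) t(m[nrow(m):1, ])
  fr <- angle_field(rot(img), rot(mask))
  h <- nrow(img)
  key <- function(r, c) paste(r, c)
  rotated <- setNames(fr$angle_deg, key(fr$row, fr$col))
  mapped <- rotated[key(f1$col, h + 1 - f1$row)]
  expect_identical(is.na(f1$angle_deg), unname(is.na(mapped)))
  ok <- !is.na(f1$angle_deg)
  expect_equal(unname((f1$angle_deg[ok] + 90) %% 180), unname(mapped[ok]),
               tolerance = 1e-9)
})

test_that("border mask pixels are dropped and counted", {
  img <- step_image(12, 6)
  mask <- matrix(TRUE, 12, 12)
  f <- angle_field(img, mask)
  expect_equal(attr(f, "n_border_dropped"), 44)
  expect_equal(nrow(f), 100)
})

test_that("undefined orientations are rare on flat noiseless interfaces", {
  sec <- generate_section(toy_profile(amp = 0), 96, 128, pixel_size = 4,
                          seed = 3, noise_sd = 0)
  band <- band_from_layermap(sec$layers)
  mask <- extract_interface(classify_band(sec$image, band), band)
  f <- angle_field(sec$image, mask)
  expect_lte(mean(is.na(f$angle_deg)), 0.05)
})

test_that("angle histograms tally angles like a hand count", {
  f0 <- tibble::tibble(angle_deg = rep(0, 7))
  h0 <- angle_histogram(f0, n_bins = 8)
  expect_equal(h0$probability, c(1, rep(0, 7)))
  expect_equal(angle_histogram(
    tibble::tibble(angle_deg = c(0, 45, 90, 135)), n_bins = 4)$probability,
    rep(0.25, 4))
  withr::with_seed(7, angles <- stats::runif(1000, 0, 180))
  h <- angle_histogram(tibble::tibble(angle_deg = angles), n_bins = 8)
  tally <- vapply(1:8, function(b) {
    sum(angles >= (b - 1) * 22.5 & angles < b * 22.5)
  }, numeric(1))
  expect_equal(h$probability, tally / 1000)
  expect_equal(sum(h$probability), 1, tolerance = 1e-12)
})
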