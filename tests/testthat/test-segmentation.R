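test_that("otsu on a band reproduces a hard step exactly", {
  img <- step_image(20, 10)
  band <- matrix(FALSE, 20, 20)
  band[7:14, ] <- TRUE
  labels <- classify_band(img, band, method = "otsu")
  expect_true(all(is.na(labels[!band])))
  expect_true(all(labels[1:10, ][band[1:10, ]] == 1))   # cartilage above
  expect_true(all(labels[11:20, ][band[11:20, ]] == 2)) # bone below
})

test_that("band-restricted otsu agrees with EBImage's whole-image otsu on a two-class image", {
  skip_if_not_installed("EBImage")
  withr::with_seed(4, {
    img <- matrix(c(stats::rnorm(200, 80, 10), stats::rnorm(200, 180, 10)),
                  20, 20)
  })
  img <- pmax(pmin(img, 255), 0)
  thr_pkg <- otsu_threshold(as.vector(img))
  thr_ebi <- EBImage::otsu(EBImage::Image(img / 255), range = c(0, 1)) * 255
  # both thresholds must induce the same partition of the two modes
  expect_identical(img >= thr_pkg, img >= thr_ebi)
})

test_that("constant-intensity bands cannot be otsu-classified", {
  img <- matrix(7, 12, 12)
  band <- matrix(TRUE, 12, 12)
  expect_error(classify_band(img, band, method = "otsu"), "constant")
  expect_silent(classify_band(img, band, method = "fixed", threshold = 5))
})

test_that("noiseless phantom band labels match the layer-map ground truth everywhere", {
  prof <- toy_profile(amp = 10)
  sec <- generate_section(prof, 128, 160, pixel_size = 4, seed = 2,
                          noise_sd = 0, blur_sigma = 0)
  band <- band_from_layermap(sec$layers)
  truth <- ifelse(sec$layers %in% c(2, 3), 1L, 2L)
  # with a mid-contrast threshold, the partial-volume transition pixel is
  # assigned by intensity majority exactly as the label map assigns it
  labels <- classify_band(sec$image, band, method = "fixed",
                          threshold = (140 + 200) / 2)
  expect_equal(mean(labels[band] == truth[band]), 1)
  # the band-restricted otsu split differs only at transition pixels
  otsu_labels <- classify_band(sec$image, band)
  expect_gte(mean(otsu_labels[band] == truth[band]), 0.995)
})

test_that("band labels survive 10%-of-contrast noise with at least 95% agreement", {
  prof <- toy_profile(amp = 10)
  agree <- vapply(1:20, function(s) {
    sec <- generate_section(prof, 96, 160, pixel_size = 4, seed = 100 + s,
                            noise_sd = 6)
    band <- band_from_layermap(sec$layers)
    labels <- classify_band(sec$image, band)
    truth <- ifelse(sec$layers %in% c(2, 3), 1L, 2L)
    mean(labels[band] == truth[band])
  }, numeric(1))
  expect_gte(mean(agree), 0.95)
})

test_that("interface thinning keeps exactly the opposite-class boundary layers", {
  img <- step_image(12, 6)
  band <- matrix(FALSE, 12, 12)
  band[4:9, ] <- TRUE
  labels <- classify_band(img, band, method = "fixed", threshold = 150)
  mask <- extract_interface(labels, band)
  # brute-force neighbour scan oracle
  oracle <- matrix(FALSE, 12, 12)
  for (r in 1:12) for (c in 1:12) {
    if (!band[r, c]) next
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if ((dr | dc) && rr >= 1 && rr <= 12 && cc >= 1 && cc <= 12 &&
          band[rr, cc] && labels[rr, cc] != labels[r, c]) {
        oracle[r, c] <- TRUE
      }
    }
  }
  expect_identical(mask, oracle)
  expect_equal(sort(unique(which(mask, arr.ind = TRUE)[, 1])), c(6, 7))
})

test_that("a diagonal boundary thins to the layers the neighbour rule implies", {
  img <- outer(1:24, 1:24, function(i, j) ifelse(i + j >= 26, 200, 100))
  band <- abs(outer(1:24, 1:24, "+") - 25.5) <= 3.5
  labels <- classify_band(img, band, method = "fixed", threshold = 150)
  mask <- extract_interface(labels, band)
  oracle <- matrix(FALSE, 24, 24)
  for (r in 1:24) for (c in 1:24) {
    if (!band[r, c]) next
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; cc <- c + dc
      if ((dr | dc) && rr >= 1 && rr <= 24 && cc >= 1 && cc <= 24 &&
          band[rr, cc] && labels[rr, cc] != labels[r, c]) {
        oracle[r, c] <- TRUE
      }
    }
  }
  expect_identical(mask, oracle)
  per_col <- colSums(mask)
  expect_true(all(per_col[per_col > 0] %in% 2:4))
})

test_that("a single-class band yields an empty mask with a warning", {
  img <- step_image(12, 6)
  band <- matrix(FALSE, 12, 12)
  band[1:4, ] <- TRUE  # all cartilage
  labels <- classify_band(img, band, method = "fixed", threshold = 150)
  expect_warning(mask <- extract_interface(labels, band), "single class")
  expect_false(any(mask))
})

test_that("classification and thinning are deterministic and mask stays inside the band", {
  prof <- toy_profile(amp = 12)
  sec <- generate_section(prof, 96, 160, pixel_size = 4, seed = 13)
  band <- band_from_layermap(sec$layers)
  m1 <- extract_interface(classify_band(sec$image, band), band)
  m2 <- extract_interface(classify_band(sec$image, band), band)
  expect_identical(m1, m2)
  expect_true(all(band[m1]))
})

test_that("layer-map bands are 7 px on flat boundaries and pair up at half-width 0", {
  sec <- generate_section(toy_profile(amp = 0), 64, 128, pixel_size = 4,
                          seed = 1, noise_sd = 0)
  band <- band_from_layermap(sec$layers, half_width_px = 3)
  expect_true(all(colSums(band) == 7))
  band0 <- band_from_layermap(sec$layers, half_width_px = 0)
  expect_true(all(colSums(band0) == 2))
  r <- sec$boundaries$bci[1]
  expect_true(all(band0[c(r - 1, r), ]))
})

test_that("sinusoidal-boundary bands equal the brute-force Chebyshev dilation", {
  sec <- generate_section(toy_profile(amp = 16), 72, 128, pixel_size = 4,
                          seed = 6, noise_sd = 0)
  band <- band_from_layermap(sec$layers, half_width_px = 3)
  plate_code <- match("subchondral_plate", layer_labels())
  top <- apply(sec$layers == plate_code, 2, function(col) min(which(col)))
  oracle <- matrix(FALSE, nrow(sec$layers), ncol(sec$layers))
  for (r in seq_len(nrow(oracle))) for (c in seq_len(ncol(oracle))) {
    for (j in seq_along(top)) {
      if (max(abs(r - top[j]), abs(c - j)) <= 3) oracle[r, c] <- TRUE
    }
  }
  expect_identical(band, structure(oracle, nominal_thickness_px = 7))
  thick <- colSums(band)
  expect_true(all(thick >= 7))
})

test_that("bands require both interface layers and report the missing one", {
  sec <- generate_section(toy_profile(), 64, 128, pixel_size = 4, seed = 1)
  no_plate <- sec$layers
  no_plate[no_plate == 4] <- 5
  attr(no_plate, "pixel_size") <- 4
  expect_error(band_from_layermap(no_plate), "subchondral_plate")
  no_calc <- sec$layers
  no_calc[no_calc == 3] <- 2
  attr(no_calc, "pixel_size") <- 4
  expect_error(band_from_layermap(no_calc), "calcified_cartilage")
})

test_that("noiseless interface masks stay within 1 px of the true boundary", {
  sec <- generate_section(toy_profile(amp = 14), 96, 160, pixel_size = 4,
                          seed = 9, noise_sd = 0)
  band <- band_from_layermap(sec$layers)
  mask <- extract_interface(classify_band(sec$image, band), band)
  centre <- apply(mask, 2, function(col) mean(which(col)))
  occupied <- !is.na(centre) & !is.nan(centre)
  truth <- sec$boundaries$bci - 0.5
  expect_true(all(abs(centre[occupied] - truth[occupied]) <= 1))
})
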