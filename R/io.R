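file_ext <- function(path) tolower(sub(".*\\.", "", path))

#' Read a histology image
#'
#' Reads a PNG or TIFF section image into a numeric intensity matrix on
#' the 0--255 scale. RGB images are reduced to the configured stain
#' channel before analysis; the red channel is the default for
#' Safranin-O-stained sections. All local-angle results depend only on
#' intensity ranks, so 8- and 16-bit inputs with the same ordering give
#' identical descriptors.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param channel `"red"`, `"green"`, `"blue"`, or `"gray"` (mean of
#'   channels); ignored for single-channel images.
#' @return Numeric matrix of intensities in \[0, 255\].
#' @export
read_histo_image <- function(path, channel = c("red", "green", "blue", "gray")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("no such image file: ", path)
  img <- switch(file_ext(path),
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", path)
  )
  if (length(dim(img)) == 3) {
    img <- switch(channel,
      red = img[, , 1],
      green = img[, , 2],
      blue = img[, , 3],
      gray = apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
    )
  }
  img * 255
}

#' Write a histology image
#'
#' Writes an intensity matrix (0--255 scale) as 8-bit grayscale PNG or
#' 16-bit grayscale TIFF, chosen by the file extension. Intensities are
#' clamped and quantised to the bit depth, so writing an already-integer
#' 8-bit raster round-trips exactly.
#'
#' @param image Numeric matrix, values in \[0, 255\].
#' @param path Destination `.png`, `.tif` or `.tiff` path.
#' @return `path`, invisibly.
#' @export
write_histo_image <- function(image, path) {
  x <- pmax(pmin(image, 255), 0) / 255
  switch(file_ext(path),
    png = png::writePNG(round(x * 255) / 255, path),
    tif = ,
    tiff = tiff::writeTIFF(round(x * 65535) / 65535, path,
                           bits.per.sample = 16L),
    stop("unsupported image format: ", path)
  )
  invisible(path)
}

#' Read and write binary masks
#'
#' Masks (bands, interface masks) are stored as single-channel PNG with 0
#' outside and 255 inside.
#'
#' @param mask Logical matrix.
#' @param path A `.png` path.
#' @return `read_mask()` returns a logical matrix; `write_mask()` returns
#'   `path` invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such mask file: ", path)
  png::readPNG(path) >= 0.5
}

#' Read and write layer maps
#'
#' A layer map is stored as an indexed grayscale PNG whose pixel values
#' are the layer codes (positions in [layer_labels()]), with a JSON
#' sidecar (`<path>.json`) recording the legend and the physical pixel
#' size.
#'
#' @param layers Integer layer-map matrix with a `pixel_size` attribute.
#' @param path A `.png` path; the sidecar is written at `<path>.json`.
#' @return `read_layer_map()` returns the integer matrix with its
#'   `pixel_size` attribute restored; `write_layer_map()` returns `path`
#'   invisibly.
#' @export
write_layer_map <- function(layers, path) {
  png::writePNG(matrix(layers / 255, nrow(layers), ncol(layers)), path)
  legend <- list(
    labels = layer_labels(),
    codes = seq_along(layer_labels()),
    pixel_size_um = attr(layers, "pixel_size")
  )
  jsonlite::write_json(legend, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_layer_map
#' @export
read_layer_map <- function(path) {
  if (!file.exists(path)) stop("no such layer-map file: ", path)
  codes <- round(png::readPNG(path) * 255)
  storage.mode(codes) <- "integer"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    legend <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(codes, "pixel_size") <- legend$pixel_size_um
  }
  codes
}

#' Read and write study tables
#'
#' Study tables use a fixed CSV dialect: comma separated, dot decimal,
#' UTF-8, header row, `NA` for missing cells (e.g. interface descriptors
#' of samples without remaining cartilage).
#'
#' @param table A study-table tibble.
#' @param path A `.csv` path.
#' @return `read_study_table()` returns a tibble; `write_study_table()`
#'   returns `path` invisibly.
#' @export
write_study_table <- function(table, path) {
  readr::write_csv(table, path, na = "NA")
  invisible(path)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stop("no such table file: ", path)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  na = c("NA", ""))
}

#' Write a report as JSON
#'
#' Serialises a (list-like) report to pretty-printed JSON with scalars
#' unboxed.
#'
#' @param report A list, e.g. a tidied [reproduce_study()] report.
#' @param path A `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
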