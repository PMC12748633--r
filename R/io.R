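#' Read a phase-diagram raster image
#'
#' Reads PNG or TIFF scans/screen captures and returns a grayscale
#' intensity matrix in `[0, 1]` (1 = white), rows top to bottom. Color
#' images are converted by averaging the color channels; an alpha
#' channel, if present, is composited over white.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix of intensities (class `matrix`), at least 3x3.
#' @export
read_diagram <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (use PNG or TIFF)")
  )
  as_intensity_matrix(img)
}

as_intensity_matrix <- function(img) {
  if (is.matrix(img)) {
    out <- img
  } else if (length(dim(img)) == 3L) {
    nch <- dim(img)[3]
    if (nch >= 3L) {
      out <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
      if (nch == 4L) out <- out * img[, , 4] + (1 - img[, , 4])
    } else {
      out <- img[, , 1]
      if (nch == 2L) out <- out * img[, , 2] + (1 - img[, , 2])
    }
  } else {
    stop("expected a 2-D image or an array with channels")
  }
  if (max(out) > 1) out <- out / 255
  if (nrow(out) < 3L || ncol(out) < 3L)
    stop("image must be at least 3x3 pixels")
  out
}

#' Write a binary mask (or intensity image) as PNG
#'
#' Masks use the convention 1 = black boundary line, 0 = white region
#' interior, so they are inverted to intensities on write.
#'
#' @param mask Binary 0/1 matrix, or a `[0, 1]` intensity matrix with
#'   `binary = FALSE`.
#' @param path Output PNG path.
#' @param binary Treat `mask` as a 0/1 boundary mask (default).
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, path, binary = TRUE) {
  img <- if (binary) 1 - mask else mask
  png::writePNG(img, path)
  invisible(path)
}
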