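# Image file I/O. PNG is handled natively; JPEG is routed through the
# jpeg package when present. All in-memory images use the 0-255 scale.

#' Read an image file
#'
#' Supports 8-bit PNG (always) and JPEG (via the optional jpeg package).
#' Returns intensities on the `[0, 255]` scale; grayscale files come back
#' as a matrix, colour files as a `height x width x 3` array (any alpha
#' channel is dropped).
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return Numeric matrix or array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop_lipdesq("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop_lipdesq("unsupported image format: '", ext, "'"))
  img <- img * 255
  if (length(dim(img)) == 3L && dim(img)[3] > 3L)
    img <- img[, , 1:3, drop = FALSE]
  if (length(dim(img)) == 3L && dim(img)[3] == 1L)
    img <- img[, , 1]
  img
}

#' Write an image to a PNG file
#'
#' @param image Numeric matrix or `height x width x 3` array on the
#'   `[0, 255]` scale; values are clamped and written as 8-bit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(clamp(image, 0, 255) / 255, path)
  invisible(path)
}

#' Write a binary mask to a PNG file
#'
#' Background pixels are written as 0 and object pixels as 255.
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
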