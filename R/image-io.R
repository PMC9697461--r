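# Image and mask I/O. Radiographs are numeric matrices (rows = y from the
# top, cols = x from the left) holding 8-bit gray values 0..255. Masks are
# 0/1 matrices of the same orientation, stored on disk as {0, 255} PNGs.

#' Read an 8-bit grayscale radiograph from PNG
#'
#' @param path PNG file path. RGB(A) files are collapsed to luminance.
#' @return Numeric matrix with values in 0..255 (rows = y, cols = x).
#' @export
read_radiograph <- function(path) {
  assert_that(file.exists(path), sprintf("no such image file: %s", path))
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  round(arr * 255)
}

#' Write a radiograph as an 8-bit grayscale PNG
#'
#' @param image Numeric matrix, values 0..255.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_radiograph <- function(image, path) {
  check_image(image)
  ok <- try(png::writePNG(round(image) / 255, path), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("failed to write image to %s", path), call. = FALSE)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' Any pixel above half intensity is foreground.
#'
#' @param path PNG file path.
#' @return 0/1 integer matrix.
#' @export
read_mask <- function(path) {
  img <- read_radiograph(path)
  (img > 127) * 1L
}

#' Write a binary mask as a {0, 255} PNG
#'
#' @param mask 0/1 matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  write_radiograph(mask * 255, path)
}
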