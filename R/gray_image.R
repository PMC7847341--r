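#' Gray-scale images
#'
#' Throughout the package a gray-scale image is a plain numeric matrix with
#' values in the working domain \[0, 1\]; rows are image rows, columns image
#' columns. Native 8-bit values are mapped to this domain by dividing by 255.
#'
#' @param img numeric matrix to validate.
#' @param arg argument name used in error messages.
#' @return `img`, invisibly, after validation.
#' @keywords internal
assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (length(img) < 1L) {
    stop(sprintf("`%s` must contain at least one pixel", arg), call. = FALSE)
  }
  if (anyNA(img)) {
    stop(sprintf("`%s` contains missing values", arg), call. = FALSE)
  }
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 1) {
    stop(sprintf("`%s` must have all values in [0, 1]", arg), call. = FALSE)
  }
  invisible(img)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Quantize a \[0,1\] image to 8-bit integers
#'
#' Values are clipped to \[0, 1\] and mapped to integers 0..255 with
#' round-half-up, the convention used by the bit-plane codec.
#'
#' @param img numeric matrix in \[0, 1\].
#' @return integer-valued matrix with entries in 0..255.
#' @export
quantize8 <- function(img) {
  v <- clip01(img)
  matrix(pmin(255, floor(v * 255 + 0.5)), nrow(img), ncol(img))
}

#' Read an 8-bit gray-scale image
#'
#' Reads a PNG or TIFF raster and returns it as a matrix in \[0, 1\]. RGB
#' inputs are converted by Rec. 601 luminance (0.299 R + 0.587 G + 0.114 B);
#' an alpha channel, if present, is ignored.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return numeric matrix in \[0, 1\].
#' @export
read_gray <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop(sprintf("cannot read image: '%s' does not exist", as.character(path)[1]),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (PNG or TIFF only)", ext),
         call. = FALSE)
  )
  if (length(dim(raw)) == 3L) {
    nc <- dim(raw)[3]
    raw <- if (nc >= 3L) {
      0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3]
    } else {
      raw[, , 1]
    }
  }
  clip01(matrix(raw, nrow(raw), ncol(raw)))
}

#' Write an 8-bit gray-scale image
#'
#' Quantizes to 0..255 (round-half-up) and writes an 8-bit gray PNG or TIFF.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  assert_gray(img)
  q <- quantize8(img) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(q, path),
    tif  = ,
    tiff = tiff::writeTIFF(q, path, bits.per.sample = 8L),
    stop(sprintf("unsupported image format '.%s' (PNG or TIFF only)", ext),
         call. = FALSE)
  )
  invisible(path)
}
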