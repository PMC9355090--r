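# Internal helpers shared across modules.

# Round half away from zero (so 0.5 -> 1, 127.5 -> 128). Used wherever
# HSV channels are scaled to integers, keeping masks bit-reproducible
# across platforms (base round() is banker's rounding).
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

# Validate an H x W x 3 RGB array with 8-bit channel values.
checkImageRGB <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop(arg, " must be an H x W x 3 array")
  d <- dim(image)
  if (d[1L] < 1L || d[2L] < 1L || length(image) == 0L)
    stop(arg, " must have height >= 1 and width >= 1")
  if (any(image < 0 | image > 255))
    stop(arg, " channel values must lie in [0, 255]")
  invisible(image)
}

checkImageHSV <- function(hsv, arg = "hsv") {
  if (!is.array(hsv) || length(dim(hsv)) != 3L || dim(hsv)[3L] != 3L)
    stop(arg, " must be an H x W x 3 array")
  if (any(hsv[, , 1L] > 180) || any(hsv[, , 2L:3L] > 255) || any(hsv < 0))
    stop(arg, " channels out of range (H <= 180, S/V <= 255)")
  invisible(hsv)
}

checkMask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) stop(arg, " must be an H x W matrix")
  if (!all(mask %in% c(0, 255))) stop(arg, " values must be 0 or 255")
  invisible(mask)
}

# Uniform-color image helper (used widely in examples and tests).
solidImage <- function(height, width, rgb) {
  array(rep(rep(as.numeric(rgb), each = height * width)),
        dim = c(height, width, 3L))
}

#' Read an RGB image file
#'
#' Decodes a PNG (via the \pkg{png} package) or any other raster format
#' supported by \pkg{EBImage} into the package's working representation:
#' an H x W x 3 array of 8-bit channel values (0--255), origin top-left.
#'
#' @param path Path to a PNG/JPEG/TIFF image.
#' @return H x W x 3 numeric array with values in [0, 255].
#' @export
readImageRGB <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    px <- png::readPNG(path)
    if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
    if (dim(px)[3L] > 3L) px <- px[, , 1:3, drop = FALSE]
    return(roundHalfUp(px * 255))
  }
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3L] > 3L) px <- px[, , 1:3, drop = FALSE]
  roundHalfUp(aperm(px, c(2L, 1L, 3L)) * 255)
}

#' Write an RGB image or a binary mask as PNG
#'
#' @param image H x W x 3 RGB array (0--255) or an H x W mask matrix with
#'   values in \{0, 255\} (written as a single-channel PNG).
#' @param path Output file path (PNG).
#' @return \code{path}, invisibly.
#' @export
writeImagePNG <- function(image, path) {
  png::writePNG(image / 255, target = path)
  invisible(path)
}
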