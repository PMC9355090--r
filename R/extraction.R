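#' SeedlingCrop: one station's slice of a capture frame
#'
#' @slot image H x W x 3 RGB array (non-seedling pixels white after
#'   extraction).
#' @slot index Station position within the frame, numbered left to right.
#' @export
setClass("SeedlingCrop",
  representation(image = "array", index = "integer"),
  validity = function(object) {
    if (length(object@index) != 1L || object@index < 1L)
      return("index must be a single positive integer")
    TRUE
  })

setMethod("show", "SeedlingCrop", function(object) {
  d <- dim(object@image)
  cat(sprintf("SeedlingCrop #%d: %d x %d\n", object@index, d[1L], d[2L]))
})

#' @describeIn SeedlingCrop-class crop image accessor
#' @param object A \code{SeedlingCrop}.
#' @export
setGeneric("cropImage", function(object) standardGeneric("cropImage"))

#' @rdname SeedlingCrop-class
#' @export
setMethod("cropImage", "SeedlingCrop", function(object) object@image)

# Colors whose union makes up the plant (leaf) extraction threshold. The
# background of a capture is white/gray, so everything chromatic from
# orange to blue is kept to retain as much seedling tissue as possible.
plantColors <- c("orange", "yellow", "green", "cyan", "blue")

#' Plant-pixel mask of an HSV image
#'
#' Union of the in-range masks for orange, yellow, green, cyan and blue:
#' the color extraction threshold for seedling tissue against a
#' white/gray background.
#'
#' @param hsv H x W x 3 HSV array (half-range hue encoding).
#' @param table Color table, as from \code{\link{colorTable}}.
#' @return Binary mask matrix.
#' @export
plantMask <- function(hsv, table = colorTable()) {
  unionMasks(lapply(table[plantColors], function(r) hsvInRange(hsv, r)))
}

#' Substrate-pixel mask of an HSV image
#'
#' The black in-range mask: the extraction threshold for the dark
#' substrate plug at the base of a seedling.
#'
#' @inheritParams plantMask
#' @return Binary mask matrix.
#' @export
substrateMask <- function(hsv, table = colorTable()) {
  hsvInRange(hsv, table$black)
}

#' Remove the background from a seedling image
#'
#' Keeps every pixel inside the union of the plant-color and
#' substrate-color masks and paints all remaining pixels white
#' (255, 255, 255), yielding the white-background single-seedling image
#' used for classification. The two-step mask composition (black-background
#' intermediate, then inversion onto white) collapses algebraically to this
#' single masked overlay; the intermediate is available for inspection via
#' \code{intermediate = TRUE}.
#'
#' @param image H x W x 3 RGB array.
#' @param table Color table, as from \code{\link{colorTable}}.
#' @param intermediate If \code{TRUE}, attach the black-background
#'   intermediate image as attribute \code{"blackBackground"}.
#' @return RGB array of the same shape with non-seedling pixels white.
#' @export
extractSeedling <- function(image, table = colorTable(),
                            intermediate = FALSE) {
  checkImageRGB(image)
  hsv <- rgbToHsv(image)
  mask <- unionMasks(plantMask(hsv, table), substrateMask(hsv, table))
  keep <- mask == 255
  out <- array(255, dim = dim(image))
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[keep] <- image[, , ch][keep]
    out[, , ch] <- plane
  }
  if (intermediate) {
    blackBg <- array(0, dim = dim(image))
    for (ch in 1:3) {
      plane <- blackBg[, , ch]
      plane[keep] <- image[, , ch][keep]
      blackBg[, , ch] <- plane
    }
    attr(out, "blackBackground") <- blackBg
  }
  out
}

#' Cut a capture frame into per-station crops
#'
#' A capture frame holds \code{n} seedlings side by side (six for the
#' standard six-station gripper). The frame is cut into \code{n}
#' equal-width vertical slices numbered 1..n left to right; when the
#' width is not divisible the remainder pixels go to the rightmost slice,
#' so concatenating the crops reconstructs the frame exactly.
#'
#' @param image H x W x 3 RGB frame.
#' @param n Number of seedling stations (default 6).
#' @return List of \code{n} \linkS4class{SeedlingCrop} objects.
#' @export
cropFrame <- function(image, n = 6L) {
  checkImageRGB(image)
  n <- as.integer(n)
  w <- dim(image)[2L]
  if (n < 1L) stop("n must be >= 1")
  if (n > w) stop("cannot cut ", w, " columns into ", n, " stations")
  base <- w %/% n
  starts <- (seq_len(n) - 1L) * base + 1L
  ends <- c(starts[-1L] - 1L, w)  # remainder goes to the rightmost slice
  lapply(seq_len(n), function(i)
    new("SeedlingCrop", image = image[, starts[i]:ends[i], , drop = FALSE],
        index = i))
}

#' Resize an image for the classification network
#'
#' Direct (non-aspect-preserving) bilinear resize to the square input
#' size the residual network accepts, 224 x 224 by default.
#'
#' @param image H x W x 3 RGB array.
#' @param size Output side length in pixels.
#' @return \code{size} x \code{size} x 3 RGB array (0--255 integers).
#' @export
resizeForNet <- function(image, size = 224L) {
  checkImageRGB(image)
  d <- dim(image)
  if (d[1L] == size && d[2L] == size) return(image)
  img <- EBImage::Image(aperm(image, c(2L, 1L, 3L)) / 255,
                        colormode = "Color")
  res <- EBImage::resize(img, w = size, h = size, filter = "bilinear")
  out <- roundHalfUp(aperm(EBImage::imageData(res), c(2L, 1L, 3L)) * 255)
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}
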