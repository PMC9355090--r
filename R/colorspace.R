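#' Convert an RGB image to HSV (half-range hue encoding)
#'
#' Implements the standard hexcone RGB-to-HSV conversion channel by
#' channel: the 8-bit channels are scaled to unit range, the chroma
#' \eqn{\Delta = C_{max} - C_{min}} is formed, hue is computed from the
#' channel holding the maximum (with the red branch wrapped into
#' [0, 360) degrees), saturation is \eqn{\Delta / C_{max}} (0 when
#' \eqn{C_{max} = 0}) and value is \eqn{C_{max}}. The result is stored in
#' the encoding used by 8-bit HSV threshold tables: hue halved to 0--180,
#' saturation and value scaled to 0--255, all rounded half away from zero.
#'
#' @param image H x W x 3 RGB array with channel values in [0, 255].
#' @return H x W x 3 HSV array: H in [0, 180], S and V in [0, 255].
#' @export
#' @examples
#' rgbToHsv(array(c(255, 0, 0), dim = c(1, 1, 3)))  # pure red -> 0,255,255
rgbToHsv <- function(image) {
  checkImageRGB(image)
  r <- image[, , 1L, drop = FALSE] / 255
  g <- image[, , 2L, drop = FALSE] / 255
  b <- image[, , 3L, drop = FALSE] / 255
  cmax <- pmax(r, g, b)
  cmin <- pmin(r, g, b)
  delta <- cmax - cmin
  # hue in degrees; branch order follows the R, G, B listing of the
  # conversion and ties go to the first matching channel
  h <- array(0, dim = dim(r))
  nz <- delta > 0
  isR <- nz & cmax == r
  isG <- nz & !isR & cmax == g
  isB <- nz & !isR & !isG
  h[isR] <- 60 * ((g[isR] - b[isR]) / delta[isR])
  h[isG] <- 60 * ((b[isG] - r[isG]) / delta[isG] + 2)
  h[isB] <- 60 * ((r[isB] - g[isB]) / delta[isB] + 4)
  h[h < 0] <- h[h < 0] + 360  # red branch can go negative; wrap to [0, 360)
  s <- ifelse(cmax == 0, 0, delta / cmax)
  out <- array(0, dim = dim(image))
  out[, , 1L] <- roundHalfUp(h / 2)
  out[, , 2L] <- roundHalfUp(s * 255)
  out[, , 3L] <- roundHalfUp(cmax * 255)
  out
}

#' Threshold an HSV image against a color range
#'
#' A pixel is set to 255 iff hue, saturation and value all fall
#' inclusively within the range's bounds; a two-interval hue range (red)
#' is satisfied when either interval holds.
#'
#' @param hsv H x W x 3 HSV array in the half-range-hue encoding.
#' @param range A \linkS4class{ColorRange}.
#' @param negate If \code{TRUE}, return the complementary mask.
#' @return H x W binary mask matrix with values in \{0, 255\}.
#' @export
#' @examples
#' tbl <- colorTable()
#' hsv <- rgbToHsv(array(c(0, 255, 0), dim = c(1, 1, 3)))
#' hsvInRange(hsv, tbl$green)
hsvInRange <- function(hsv, range, negate = FALSE) {
  checkImageHSV(hsv)
  stopifnot(is(range, "ColorRange"))
  d <- dim(hsv)
  h <- matrix(hsv[, , 1L], d[1L], d[2L])
  s <- matrix(hsv[, , 2L], d[1L], d[2L])
  v <- matrix(hsv[, , 3L], d[1L], d[2L])
  inH <- matrix(FALSE, d[1L], d[2L])
  for (j in seq_len(ncol(range@hue)))
    inH <- inH | (h >= range@hue[1L, j] & h <= range@hue[2L, j])
  hit <- inH & s >= range@sMin & s <= range@sMax &
    v >= range@vMin & v <= range@vMax
  if (negate) hit <- !hit
  ifelse(hit, 255, 0)
}

#' Union of binary masks
#'
#' Combines threshold masks by pixelwise union (a pixel is foreground if
#' it is foreground in at least one mask) -- the "sum" of binary images
#' used when plant-color and substrate-color masks are merged.
#'
#' @param ... Binary mask matrices (values in \{0, 255\}), or a single
#'   list of them.
#' @return The union mask.
#' @export
unionMasks <- function(...) {
  masks <- list(...)
  if (length(masks) == 1L && is.list(masks[[1L]]) && !is.matrix(masks[[1L]]))
    masks <- masks[[1L]]
  if (length(masks) == 0L) stop("no masks supplied")
  d <- dim(masks[[1L]])
  for (m in masks) {
    checkMask(m)
    if (!identical(dim(m), d)) stop("all masks must share one shape")
  }
  Reduce(pmax, masks)
}

#' The HSV color threshold table
#'
#' Loads the 10-color HSV threshold table (black, gray, white, red,
#' orange, yellow, green, cyan, blue, purple) shipped with the package as
#' a versioned JSON resource, or a user-supplied override with the same
#' schema. Hues are in the half-range encoding (0--180), saturation and
#' value in 0--255; red carries two hue intervals (0--10 and 156--180).
#'
#' The shipped bounds are the canonical 8-bit HSV segmentation table for
#' these ten colors (printed reproductions of it are often garbled, with
#' more hue columns than labels; the JSON resource is the consistent
#' reconstruction and can be replaced wholesale via \code{path}).
#'
#' @param path Optional path to a JSON color table overriding the
#'   built-in resource.
#' @return Named list of \linkS4class{ColorRange} objects.
#' @export
#' @examples
#' names(colorTable())
colorTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hsv_color_table.json",
                        package = "SeedlingScreen", mustWork = TRUE)
  spec <- jsonlite::read_json(path)
  out <- lapply(spec$colors, function(cl)
    colorRange(cl$name, unlist(cl$hMin), unlist(cl$hMax),
               cl$sMin, cl$sMax, cl$vMin, cl$vMax))
  names(out) <- vapply(out, function(r) r@name, character(1L))
  out
}
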