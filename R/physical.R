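#' Denoising configuration for the rule-based screen
#'
#' Settings for \code{\link{denoiseMask}}: a morphological closing
#' (dilation then erosion) with a small structuring element, followed by
#' Gaussian smoothing and a mid-level re-threshold that restores a binary
#' mask. The defaults are deliberately minimal denoisers: a 3 x 3
#' elliptical (diamond) brush applied once, and a 5 x 5 Gaussian with
#' sigma 1.1 re-thresholded at 127.
#'
#' @param brushSize Structuring element side length (odd).
#' @param brushShape Structuring element shape (EBImage brush shape).
#' @param iterations Number of dilate/erode passes.
#' @param gaussianSize Gaussian kernel side length (odd).
#' @param gaussianSigma Gaussian standard deviation in pixels.
#' @param threshold Re-binarisation level on the 0--255 scale; smoothed
#'   values strictly above it become foreground.
#' @return Named list of settings.
#' @export
morphologyConfig <- function(brushSize = 3L, brushShape = "diamond",
                             iterations = 1L, gaussianSize = 5L,
                             gaussianSigma = 1.1, threshold = 127) {
  list(brushSize = as.integer(brushSize), brushShape = brushShape,
       iterations = as.integer(iterations),
       gaussianSize = as.integer(gaussianSize),
       gaussianSigma = gaussianSigma, threshold = threshold)
}

#' Denoise a binary mask
#'
#' Applies morphological dilation then erosion (closing small gaps in the
#' thresholded leaf/substrate regions), then Gaussian smoothing followed
#' by a mid-level re-threshold, which suppresses isolated noise pixels
#' while leaving solid regions essentially unchanged.
#'
#' @param mask H x W binary mask matrix (values in \{0, 255\}).
#' @param config Settings from \code{\link{morphologyConfig}}.
#' @return Denoised binary mask of the same shape.
#' @export
denoiseMask <- function(mask, config = morphologyConfig()) {
  checkMask(mask)
  img <- EBImage::Image(t(mask) / 255)
  brush <- EBImage::makeBrush(config$brushSize, shape = config$brushShape)
  for (i in seq_len(config$iterations)) img <- EBImage::dilate(img, brush)
  for (i in seq_len(config$iterations)) img <- EBImage::erode(img, brush)
  g <- EBImage::makeBrush(config$gaussianSize, shape = "Gaussian",
                          sigma = config$gaussianSigma)
  g <- g / sum(g)
  img <- EBImage::filter2(img, g, boundary = "replicate")
  out <- ifelse(t(EBImage::imageData(img)) * 255 > config$threshold, 255, 0)
  out
}

#' Measure leaf and substrate pixel areas
#'
#' Converts the image to HSV, thresholds the yellow-green leaf pixels
#' (yellow and green ranges; the leaf measurement is deliberately
#' narrower than the five-color plant extraction set) and the black
#' substrate pixels, denoises both binary images and counts the
#' foreground pixels of each.
#'
#' @param image H x W x 3 RGB array (typically a white-background
#'   extracted seedling crop).
#' @param table Color table, as from \code{\link{colorTable}}.
#' @param leafColors Color names whose union defines leaf tissue.
#' @param config Denoising settings from \code{\link{morphologyConfig}}.
#' @return Named numeric vector \code{c(leaf = , substrate = )} of pixel
#'   counts.
#' @export
measureAreas <- function(image, table = colorTable(),
                         leafColors = c("yellow", "green"),
                         config = morphologyConfig()) {
  checkImageRGB(image)
  hsv <- rgbToHsv(image)
  leaf <- unionMasks(lapply(table[leafColors], function(r)
    hsvInRange(hsv, r)))
  substrate <- hsvInRange(hsv, table$black)
  leaf <- denoiseMask(leaf, config)
  substrate <- denoiseMask(substrate, config)
  c(leaf = sum(leaf == 255), substrate = sum(substrate == 255))
}

#' Classify a seedling from its measured areas
#'
#' The rule-based verdict: if both measured areas are zero (up to the
#' configurable noise tolerance \code{epsilon}) the station is empty
#' (\code{none}); if the leaf area and the substrate area both reach
#' their healthy-seedling minima the verdict is \code{healthy}; in every
#' other case the seedling is \code{unhealthy}. The three regions
#' partition the nonnegative quadrant, so exactly one label applies to
#' any input.
#'
#' @param leafArea Measured leaf pixel area (>= 0).
#' @param substrateArea Measured substrate pixel area (>= 0).
#' @param thresholds A \linkS4class{ScreeningThresholds} (defaults to
#'   leaf >= 2300, substrate >= 1300).
#' @param epsilon Areas at or below this count as zero for the
#'   empty-station test (default 0: strict).
#' @return A \linkS4class{ScreeningResult}.
#' @export
#' @examples
#' screenLabel(classifyPhysical(2500, 1400))  # healthy
#' screenLabel(classifyPhysical(0, 0))        # none
#' screenLabel(classifyPhysical(2500, 1000))  # unhealthy
classifyPhysical <- function(leafArea, substrateArea,
                             thresholds = screeningThresholds(),
                             epsilon = 0) {
  if (leafArea < 0 || substrateArea < 0)
    stop("areas must be nonnegative")
  label <- if (leafArea <= epsilon && substrateArea <= epsilon) {
    "none"
  } else if (leafArea >= thresholds@leafMin &&
             substrateArea >= thresholds@substrateMin) {
    "healthy"
  } else {
    "unhealthy"
  }
  if (label == "none") leafArea <- substrateArea <- 0
  new("ScreeningResult", label = label, leafArea = as.numeric(leafArea),
      substrateArea = as.numeric(substrateArea))
}

#' Rule-based screen of a single seedling image
#'
#' Convenience wrapper: measure areas, then classify.
#'
#' @inheritParams measureAreas
#' @inheritParams classifyPhysical
#' @return A \linkS4class{ScreeningResult}.
#' @export
screenPhysical <- function(image, table = colorTable(),
                           thresholds = screeningThresholds(),
                           config = morphologyConfig(), epsilon = 0) {
  a <- measureAreas(image, table = table, config = config)
  classifyPhysical(a[["leaf"]], a[["substrate"]], thresholds = thresholds,
                   epsilon = epsilon)
}
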