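#' Parameters for rendering a synthetic side-view seedling image
#'
#' The generator emulates the geometry of a side-view capture of a
#' plug-tray seedling held in front of the camera: a light neutral
#' (white/gray) background with per-pixel jitter, a dark substrate plug
#' block at the bottom center, and a number of green elliptical leaf
#' blobs above it. The blob count is an explicit proxy for the
#' "three leaves and one heart" maturity criterion, which has no
#' geometric definition here; leaf and substrate pixel areas are hit
#' exactly, so the record's ground truth is the rendered truth.
#'
#' @param frameWidth,frameHeight Canvas size in pixels (default
#'   640 x 480, the nominal capture size).
#' @param leafBlobCount Number of leaf blobs (0 for an empty frame).
#' @param targetLeafArea Total leaf pixel area to render.
#' @param targetSubstrateArea Substrate pixel area to render.
#' @param wilt If \code{TRUE}, draw flattened (wilted) leaf blobs close
#'   to the substrate.
#' @param background Base background gray level (8-bit).
#' @param backgroundJitter Amplitude of the per-pixel background jitter.
#' @param seed Optional seed; when \code{NULL} the surrounding RNG
#'   stream is used.
#' @return Named parameter list for \code{\link{renderSeedling}}.
#' @export
synthParams <- function(frameWidth = 640L, frameHeight = 480L,
                        leafBlobCount = 3L, targetLeafArea = 3000,
                        targetSubstrateArea = 1500, wilt = FALSE,
                        background = 235, backgroundJitter = 5,
                        seed = NULL) {
  list(frameWidth = as.integer(frameWidth),
       frameHeight = as.integer(frameHeight),
       leafBlobCount = as.integer(leafBlobCount),
       targetLeafArea = round(targetLeafArea),
       targetSubstrateArea = round(targetSubstrateArea),
       wilt = isTRUE(wilt), background = background,
       backgroundJitter = backgroundJitter, seed = seed)
}

# Label rule shared by the generator and its records: a render is
# healthy iff leaf area >= leafMin, substrate area >= substrateMin and
# at least three leaf blobs are present; an empty frame is "none";
# everything else is unhealthy.
.synthLabel <- function(leafArea, substrateArea, blobCount,
                        thresholds = screeningThresholds()) {
  if (leafArea == 0 && substrateArea == 0 && blobCount == 0L) return("none")
  if (leafArea >= thresholds@leafMin &&
      substrateArea >= thresholds@substrateMin && blobCount >= 3L)
    return("healthy")
  "unhealthy"
}

# Pick exactly `area` free pixels forming an ellipse around (cy, cx).
.ellipsePixels <- function(cy, cx, area, aspect, h, w, occupied) {
  if (area <= 0) return(integer(0))
  scale <- 1.3
  repeat {
    b <- sqrt(area / (pi * aspect))
    a <- aspect * b
    rr <- ceiling(b * scale) + 1L
    rc <- ceiling(a * scale) + 1L
    rows <- max(1L, round(cy) - rr):min(h, round(cy) + rr)
    cols <- max(1L, round(cx) - rc):min(w, round(cx) + rc)
    g <- expand.grid(r = rows, c = cols)
    d <- ((g$c - cx) / a)^2 + ((g$r - cy) / b)^2
    ord <- order(d, g$r, g$c)
    lin <- g$r[ord] + (g$c[ord] - 1L) * h
    lin <- lin[!occupied[lin]]
    if (length(lin) >= area) return(lin[seq_len(area)])
    scale <- scale * 1.5
    if (scale > 20) stop("infeasible leaf area: blob does not fit the frame")
  }
}

#' Render one synthetic seedling image with ground truth
#'
#' Draws the background, the substrate block (its pixel area equals
#' \code{targetSubstrateArea} exactly) and \code{leafBlobCount} green
#' elliptical leaf blobs whose total pixel area equals
#' \code{targetLeafArea} exactly. The returned record carries the
#' rendered areas (counted from the render masks), the blob count, the
#' rule-derived label and the parameters.
#'
#' @param params Parameter list from \code{\link{synthParams}}.
#' @param thresholds \linkS4class{ScreeningThresholds} used for the
#'   record's label rule.
#' @return List with \code{image} (H x W x 3 RGB array) and
#'   \code{record} (list: \code{label}, \code{leafArea},
#'   \code{substrateArea}, \code{blobCount}, \code{params}).
#' @export
#' @examples
#' r <- renderSeedling(synthParams(leafBlobCount = 3, seed = 7))
#' r$record$label
renderSeedling <- function(params = synthParams(),
                           thresholds = screeningThresholds()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  h <- params$frameHeight; w <- params$frameWidth
  if (h < 8L || w < 8L) stop("frame too small")
  capacity <- 0.4 * h * w
  if (params$targetLeafArea > capacity ||
      params$targetSubstrateArea > capacity)
    stop("infeasible areas: targets exceed 40% of the frame")
  if (params$targetLeafArea > 0 && params$leafBlobCount < 1L)
    stop("positive leaf area needs at least one blob")

  # background: light neutral with shared luminance jitter plus a small
  # independent channel jitter (stays inside the white HSV range)
  n <- h * w
  lum <- params$background +
    stats::runif(n, -params$backgroundJitter, params$backgroundJitter)
  img <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3)
    img[, , ch] <- pmin(252, pmax(223,
      roundHalfUp(lum + stats::runif(n, -2, 2))))

  occupied <- rep(FALSE, n)  # linear index r + (c-1)*h
  substratePix <- integer(0)
  subTop <- h
  if (params$targetSubstrateArea > 0) {
    ws <- min(w, max(8L, round(sqrt(3 * params$targetSubstrateArea))))
    c0 <- max(1L, floor((w - ws) / 2) + 1L)
    cols <- c0:(c0 + ws - 1L)
    fullRows <- params$targetSubstrateArea %/% ws
    rem <- params$targetSubstrateArea %% ws
    if (fullRows >= h) stop("infeasible substrate area for this frame")
    rows <- if (fullRows > 0) (h - fullRows + 1L):h else integer(0)
    substratePix <- as.integer(outer(rows, (cols - 1L) * h, "+"))
    if (rem > 0) {
      rtop <- h - fullRows
      cstart <- c0 + ((ws - rem) %/% 2)
      substratePix <- c(substratePix,
                        rtop + (seq.int(cstart, length.out = rem) - 1L) * h)
    }
    occupied[substratePix] <- TRUE
    subTop <- h - fullRows - (rem > 0)
  }

  leafPix <- integer(0)
  k <- params$leafBlobCount
  if (params$targetLeafArea > 0 && k > 0L) {
    per <- rep(params$targetLeafArea %/% k, k)
    per[seq_len(params$targetLeafArea %% k)] <-
      per[seq_len(params$targetLeafArea %% k)] + 1L
    cx0 <- (w + 1) / 2
    blobCols <- vector("list", k)
    for (i in seq_len(k)) {
      aspect <- if (params$wilt) stats::runif(1, 3.2, 4.5)
                else stats::runif(1, 1.1, 1.7)
      b <- sqrt(per[i] / (pi * aspect))
      spread <- max(4, 2.2 * aspect * b)
      cx <- cx0 + (i - (k + 1) / 2) * spread + stats::runif(1, -3, 3)
      cx <- min(max(cx, aspect * b + 2), w - aspect * b - 2)
      top <- if (params$wilt) subTop - 1.6 * b else subTop - 2.2 * b
      cy <- top - stats::runif(1, 0, max(4, 0.12 * h))
      cy <- min(max(cy, b + 2), max(b + 2, subTop - b - 1))
      pix <- .ellipsePixels(cy, cx, per[i], aspect, h, w, occupied)
      occupied[pix] <- TRUE
      blobCols[[i]] <- pix
    }
    leafPix <- unlist(blobCols)
    for (i in seq_len(k)) {
      base <- c(40, 150, 55) +
        c(stats::runif(1, -15, 15), stats::runif(1, -30, 30),
          stats::runif(1, -15, 15))
      pix <- blobCols[[i]]
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[pix] <- pmin(255, pmax(0,
          roundHalfUp(base[ch] + stats::runif(length(pix), -8, 8))))
        img[, , ch] <- plane
      }
    }
  }
  if (length(substratePix)) {
    base <- c(32, 27, 22)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[substratePix] <- pmin(45, pmax(2,
        roundHalfUp(base[ch] +
                    stats::runif(length(substratePix), -8, 8))))
      img[, , ch] <- plane
    }
  }

  leafArea <- length(leafPix)
  substrateArea <- length(substratePix)
  blobCount <- if (leafArea > 0) k else 0L
  record <- list(label = .synthLabel(leafArea, substrateArea, blobCount,
                                     thresholds),
                 leafArea = leafArea, substrateArea = substrateArea,
                 blobCount = blobCount, params = params)
  list(image = img, record = record)
}

# Per-class parameter sampling. Healthy renders sit at least `margin`
# above both area thresholds; unhealthy renders fall at least `margin`
# below at least one (a leaf deficit, a substrate loss, or a wilt with
# reduced leaf area), mirroring the defect types the screen targets.
.sampleClassParams <- function(label, thresholds, margin, frameWidth,
                               frameHeight) {
  lMin <- thresholds@leafMin; sMin <- thresholds@substrateMin
  okLeaf <- round(stats::runif(1, (1 + margin) * lMin, 1.8 * lMin))
  okSub <- round(stats::runif(1, (1 + margin) * sMin, 1.8 * sMin))
  if (label == "none")
    return(synthParams(frameWidth, frameHeight, leafBlobCount = 0L,
                       targetLeafArea = 0, targetSubstrateArea = 0))
  if (label == "healthy")
    return(synthParams(frameWidth, frameHeight,
                       leafBlobCount = sample(3:4, 1L),
                       targetLeafArea = okLeaf,
                       targetSubstrateArea = okSub))
  mode <- sample(c("leafDeficit", "substrateLoss", "wilt"), 1L)
  lowLeaf <- round(stats::runif(1, 0.3 * lMin, (1 - margin) * lMin))
  lowSub <- round(stats::runif(1, 0.15 * sMin, (1 - margin) * sMin))
  switch(mode,
    leafDeficit = synthParams(frameWidth, frameHeight,
                              leafBlobCount = sample(2:3, 1L),
                              targetLeafArea = lowLeaf,
                              targetSubstrateArea = okSub),
    substrateLoss = synthParams(frameWidth, frameHeight,
                                leafBlobCount = sample(3:4, 1L),
                                targetLeafArea = okLeaf,
                                targetSubstrateArea = lowSub),
    wilt = synthParams(frameWidth, frameHeight,
                       leafBlobCount = sample(2:3, 1L),
                       targetLeafArea = lowLeaf,
                       targetSubstrateArea = okSub, wilt = TRUE))
}

#' Generate a labelled synthetic seedling dataset
#'
#' Renders \code{nPerClass} images for each class (healthy, unhealthy,
#' none), writes them as PNGs with a \code{manifest.csv} (columns
#' \code{path,label,split}, stratified 60/20/20 by default) and a
#' \code{ground_truth.json} holding every record's exact rendered areas
#' and parameters. Healthy renders keep both areas at least
#' \code{margin} (default 20\%) above the screening thresholds and
#' unhealthy renders at least \code{margin} below on one criterion, so
#' rule-based screening and the generator labels agree by construction.
#' Identical seeds give byte-identical outputs.
#'
#' @param nPerClass Images per class (>= 1).
#' @param seed Integer seed for all rendering and the split.
#' @param outDir Output directory (created if needed).
#' @param frameWidth,frameHeight Canvas size per image.
#' @param thresholds \linkS4class{ScreeningThresholds} for the label
#'   rule.
#' @param margin Relative separation of sampled areas from the
#'   thresholds.
#' @param splitFractions Train/val/test fractions for
#'   \code{\link{splitDataset}}.
#' @return The manifest data frame (with split assigned); the per-image
#'   records are attached as attribute \code{"records"}.
#' @export
generateDataset <- function(nPerClass, seed = 1L, outDir = tempfile("synth"),
                            frameWidth = 640L, frameHeight = 480L,
                            thresholds = screeningThresholds(),
                            margin = 0.2,
                            splitFractions = c(0.6, 0.2, 0.2)) {
  if (nPerClass < 1L) stop("nPerClass must be >= 1")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outDir, 2L) != 0L)
    stop("output directory is not writable: ", outDir)
  set.seed(seed)
  rows <- list()
  records <- list()
  i <- 0L
  for (label in seedlingClasses()) {
    for (j in seq_len(nPerClass)) {
      i <- i + 1L
      p <- .sampleClassParams(label, thresholds, margin, frameWidth,
                              frameHeight)
      r <- renderSeedling(p, thresholds)
      stopifnot(r$record$label == label)
      fname <- sprintf("%s_%04d.png", label, j)
      writeImagePNG(r$image, file.path(outDir, fname))
      rows[[i]] <- data.frame(path = file.path(outDir, fname),
                              label = label, split = NA_character_,
                              stringsAsFactors = FALSE)
      records[[i]] <- r$record
    }
  }
  manifest <- do.call(rbind, rows)
  manifest <- splitDataset(manifest, fractions = splitFractions,
                           seed = seed)
  writeManifest(manifest, file.path(outDir, "manifest.csv"))
  jsonlite::write_json(records, file.path(outDir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  attr(manifest, "records") <- records
  manifest
}

#' Render a multi-seedling capture frame
#'
#' Composes one frame from per-station renders, mirroring a capture of a
#' multi-seedling gripper: station i occupies the i-th equal-width
#' vertical slice (remainder columns to the rightmost station, matching
#' \code{\link{cropFrame}}).
#'
#' @param stationParams List of per-station parameter lists from
#'   \code{\link{synthParams}} (their frame sizes are overridden by the
#'   slice geometry); use \code{NULL} for an empty station.
#' @param frameWidth,frameHeight Full frame size.
#' @param thresholds Passed to \code{\link{renderSeedling}}.
#' @return List with \code{image} (the frame) and \code{records} (one
#'   per station).
#' @export
renderFrame <- function(stationParams, frameWidth = 640L,
                        frameHeight = 480L,
                        thresholds = screeningThresholds()) {
  n <- length(stationParams)
  base <- frameWidth %/% n
  widths <- rep(base, n)
  widths[n] <- frameWidth - base * (n - 1L)
  img <- array(0, dim = c(frameHeight, frameWidth, 3L))
  records <- vector("list", n)
  col <- 1L
  for (i in seq_len(n)) {
    p <- stationParams[[i]]
    if (is.null(p)) p <- synthParams(leafBlobCount = 0L,
                                     targetLeafArea = 0,
                                     targetSubstrateArea = 0)
    p$frameWidth <- widths[i]
    p$frameHeight <- as.integer(frameHeight)
    r <- renderSeedling(p, thresholds)
    img[, col:(col + widths[i] - 1L), ] <- r$image
    records[[i]] <- r$record
    col <- col + widths[i]
  }
  list(image = img, records = records)
}
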