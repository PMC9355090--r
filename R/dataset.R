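#' Read / write a dataset manifest
#'
#' A manifest is a CSV with header \code{path,label,split}: one row per
#' image, labels from \code{\link{seedlingClasses}}, split one of
#' \code{train}, \code{val}, \code{test} (or \code{NA} before
#' \code{\link{splitDataset}} has been applied).
#'
#' @param path CSV file path.
#' @return Data frame with columns \code{path}, \code{label},
#'   \code{split}.
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns path and label")
  if (is.null(m$split)) m$split <- NA_character_
  m[, c("path", "label", "split")]
}

#' @rdname readManifest
#' @param manifest Manifest data frame.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest[, c("path", "label", "split")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified train/validation/test split
#'
#' Assigns each manifest row to \code{train}, \code{val} or \code{test}
#' by per-class stratified random sampling at the requested fractions
#' (default 60/20/20). Within each class the counts are
#' floor-then-distribute: each split gets the floor of its share and the
#' remaining images go to the splits with the largest fractional
#' remainders (ties favouring train, then val), so per-class counts
#' deviate from the exact fractions by at most one image. The assignment
#' is deterministic for a fixed \code{seed}.
#'
#' @param manifest Data frame with columns \code{path} and \code{label};
#'   every class must be present.
#' @param fractions Numeric vector of three split fractions summing
#'   to 1.
#' @param seed Integer seed for the shuffle.
#' @return The manifest with its \code{split} column filled in.
#' @export
#' @examples
#' m <- data.frame(path = sprintf("img%03d.png", 1:30),
#'                 label = rep(seedlingClasses(), each = 10))
#' table(splitDataset(m, seed = 1)$split)
splitDataset <- function(manifest, fractions = c(0.6, 0.2, 0.2),
                         seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three values summing to 1")
  if (any(fractions < 0)) stop("fractions must be nonnegative")
  if (anyDuplicated(manifest$path)) stop("manifest paths must be unique")
  splits <- c("train", "val", "test")
  bad <- setdiff(unique(manifest$label), seedlingClasses())
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(manifest$label, levels = seedlingClasses()))
  if (!nrow(manifest) || any(counts == 0L))
    stop("empty class: every class needs at least one image (",
         paste(names(counts)[counts == 0L], collapse = ", "), ")")
  classes <- seedlingClasses()
  set.seed(seed)
  manifest$split <- NA_character_
  for (cl in classes) {
    rows <- which(manifest$label == cl)
    n <- length(rows)
    if (n == 0L) stop("empty class: ", cl)
    base <- floor(fractions * n)
    rem <- n - sum(base)
    if (rem > 0) {
      frac <- fractions * n - base
      # largest fractional remainder first; ties favour train, then val
      extra <- order(-frac, seq_along(frac))[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    perm <- sample(rows)
    manifest$split[perm] <- rep(splits, times = base)
  }
  manifest
}

#' Augmentation configuration
#'
#' Ranges for the random geometric augmentation used to expand
#' under-represented classes: shear up to 25 degrees, rotation up to 20
#' degrees, horizontal flipping, and horizontal/vertical shifts up to
#' 0.3 of the image dimension. Vacated pixels are filled with white to
#' match the extracted-image background.
#'
#' @param shearDegrees Maximum absolute shear angle (degrees).
#' @param rotationDegrees Maximum absolute rotation (degrees).
#' @param horizontalFlip Allow a random (probability 0.5) horizontal
#'   flip.
#' @param widthShiftFraction Maximum horizontal shift as a fraction of
#'   the width, in [0, 1].
#' @param heightShiftFraction Maximum vertical shift as a fraction of
#'   the height, in [0, 1].
#' @return Named list of ranges.
#' @export
augmentationConfig <- function(shearDegrees = 25, rotationDegrees = 20,
                               horizontalFlip = TRUE,
                               widthShiftFraction = 0.3,
                               heightShiftFraction = 0.3) {
  stopifnot(shearDegrees >= 0, rotationDegrees >= 0,
            widthShiftFraction >= 0, widthShiftFraction <= 1,
            heightShiftFraction >= 0, heightShiftFraction <= 1)
  list(shearDegrees = shearDegrees, rotationDegrees = rotationDegrees,
       horizontalFlip = isTRUE(horizontalFlip),
       widthShiftFraction = widthShiftFraction,
       heightShiftFraction = heightShiftFraction)
}

#' Mirror an image left-to-right
#'
#' @param image H x W x 3 RGB array.
#' @return The horizontally flipped image.
#' @export
flipHorizontal <- function(image) {
  checkImageRGB(image)
  image[, rev(seq_len(dim(image)[2L])), , drop = FALSE]
}

# Bilinear sampling of `image` at fractional (row, col) coordinates;
# coordinates outside the canvas return white.
.bilinearSample <- function(image, rows, cols) {
  h <- dim(image)[1L]; w <- dim(image)[2L]
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  out <- array(255, dim = c(length(rows), 3L))
  get <- function(r, c, ch) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    v <- rep(255, length(r))
    v[ok] <- image[cbind(r[ok], c[ok], ch)]
    v
  }
  for (ch in 1:3) {
    v <- (1 - fr) * (1 - fc) * get(r0, c0, ch) +
         (1 - fr) * fc       * get(r0, c0 + 1, ch) +
         fr       * (1 - fc) * get(r0 + 1, c0, ch) +
         fr       * fc       * get(r0 + 1, c0 + 1, ch)
    out[, ch] <- v
  }
  out
}

#' Randomly augment an image
#'
#' Applies one randomly parameterised composition of horizontal flip,
#' shear, rotation and horizontal/vertical shift (each drawn uniformly
#' within the configured range), resampling bilinearly about the image
#' center. The output has the input's size; pixels mapped from outside
#' the canvas are white. With a fixed \code{seed} the output is
#' bit-identical across runs, and an all-zero configuration returns the
#' image unchanged.
#'
#' @param image H x W x 3 RGB array.
#' @param config Ranges from \code{\link{augmentationConfig}}.
#' @param seed Optional integer seed for the parameter draw.
#' @return Augmented RGB array of the same shape.
#' @export
augmentImage <- function(image, config = augmentationConfig(),
                         seed = NULL) {
  checkImageRGB(image)
  if (!is.null(seed)) set.seed(seed)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  shear <- stats::runif(1, -config$shearDegrees,
                        config$shearDegrees) * pi / 180
  rot <- stats::runif(1, -config$rotationDegrees,
                      config$rotationDegrees) * pi / 180
  flip <- config$horizontalFlip && stats::runif(1) < 0.5
  dx <- stats::runif(1, -config$widthShiftFraction,
                     config$widthShiftFraction) * w
  dy <- stats::runif(1, -config$heightShiftFraction,
                     config$heightShiftFraction) * h
  # forward map about the center: flip, then shear, rotate, shift
  Fm <- diag(c(1, if (flip) -1 else 1))
  Sh <- matrix(c(1, 0, tan(shear), 1), 2L, 2L)
  Ro <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2L, 2L)
  A <- Ro %*% Sh %*% Fm
  if (abs(det(A)) < 1e-12) return(array(255, dim = dim(image)))
  Ainv <- solve(A)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  grid <- expand.grid(r = seq_len(h), c = seq_len(w))
  oy <- grid$r - cy - dy
  ox <- grid$c - cx - dx
  src <- Ainv %*% rbind(oy, ox)
  vals <- .bilinearSample(image, src[1L, ] + cy, src[2L, ] + cx)
  out <- array(0, dim = dim(image))
  for (ch in 1:3) out[, , ch] <- matrix(vals[, ch], h, w)
  pmin(pmax(roundHalfUp(out), 0), 255)
}
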