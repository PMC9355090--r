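#' @import methods
NULL

#' Class labels used throughout the package
#'
#' The three-way seedling classification uses a fixed encoding order:
#' \code{healthy} (class 1, transplantable seedling), \code{unhealthy}
#' (class 2, defective seedling to be removed), \code{none} (class 3, an
#' empty frame, e.g. a failed pick). All classifiers, confusion matrices
#' and manifests use this order.
#'
#' @return Character vector of the three class labels, in encoding order.
#' @export
#' @examples
#' seedlingClasses()
seedlingClasses <- function() c("healthy", "unhealthy", "none")

#' ColorRange: an HSV threshold box
#'
#' A named HSV in-range box in the half-range-hue encoding (hue 0--180,
#' i.e. degrees halved; saturation and value 0--255). A range may carry
#' one or two hue intervals; two are needed for red, whose hue wraps
#' around 0/360 degrees.
#'
#' @slot name Color label, e.g. \code{"green"}.
#' @slot hue 2 x k numeric matrix (k = 1 or 2) with rows \code{min},
#'   \code{max}; each interval inclusive, bounds in [0, 180].
#' @slot sMin,sMax Saturation bounds in [0, 255].
#' @slot vMin,vMax Value bounds in [0, 255].
#' @export
setClass("ColorRange",
  representation(name = "character", hue = "matrix",
                 sMin = "numeric", sMax = "numeric",
                 vMin = "numeric", vMax = "numeric"),
  validity = function(object) {
    h <- object@hue
    if (nrow(h) != 2L || !ncol(h) %in% c(1L, 2L))
      return("hue must be a 2 x 1 or 2 x 2 matrix (rows min, max)")
    if (any(h < 0) || any(h > 180)) return("hue bounds must lie in [0, 180]")
    if (any(h[1L, ] > h[2L, ])) return("each hue min must be <= its max")
    for (ch in c("sMin", "sMax", "vMin", "vMax")) {
      v <- slot(object, ch)
      if (length(v) != 1L || v < 0 || v > 255)
        return(paste(ch, "must be a single value in [0, 255]"))
    }
    if (object@sMin > object@sMax) return("sMin must be <= sMax")
    if (object@vMin > object@vMax) return("vMin must be <= vMax")
    TRUE
  })

#' Construct a ColorRange
#'
#' @param name Color label.
#' @param hMin,hMax Hue bounds (half-range encoding, 0--180); supply
#'   vectors of length 2 for a two-interval range such as red.
#' @param sMin,sMax,vMin,vMax Saturation/value bounds (0--255).
#' @return A \linkS4class{ColorRange}.
#' @export
#' @examples
#' colorRange("green", 35, 77, 43, 255, 46, 255)
#' colorRange("red", c(0, 156), c(10, 180), 43, 255, 46, 255)
colorRange <- function(name, hMin, hMax, sMin, sMax, vMin, vMax) {
  new("ColorRange", name = as.character(name),
      hue = rbind(min = as.numeric(hMin), max = as.numeric(hMax)),
      sMin = as.numeric(sMin), sMax = as.numeric(sMax),
      vMin = as.numeric(vMin), vMax = as.numeric(vMax))
}

setMethod("show", "ColorRange", function(object) {
  iv <- apply(object@hue, 2L, function(h) sprintf("%g-%g", h[1L], h[2L]))
  cat(sprintf("ColorRange '%s': H %s, S %g-%g, V %g-%g\n", object@name,
              paste(iv, collapse = " | "), object@sMin, object@sMax,
              object@vMin, object@vMax))
})

#' ScreeningThresholds: pixel-area cut-offs for the rule-based screen
#'
#' @slot leafMin Minimum leaf pixel area of a healthy seedling.
#' @slot substrateMin Minimum substrate pixel area of a healthy seedling.
#' @export
setClass("ScreeningThresholds",
  representation(leafMin = "numeric", substrateMin = "numeric"),
  validity = function(object) {
    if (object@leafMin < 0 || object@substrateMin < 0)
      return("thresholds must be nonnegative")
    TRUE
  })

#' Construct screening thresholds
#'
#' Defaults are the pixel-area cut-offs for 640 x 480 side-view captures:
#' a healthy seedling must show at least 2,300 leaf pixels and 1,300
#' substrate pixels.
#'
#' @param leafMin Minimum leaf pixel area (default 2300).
#' @param substrateMin Minimum substrate pixel area (default 1300).
#' @return A \linkS4class{ScreeningThresholds}.
#' @export
screeningThresholds <- function(leafMin = 2300, substrateMin = 1300) {
  new("ScreeningThresholds", leafMin = leafMin, substrateMin = substrateMin)
}

setMethod("show", "ScreeningThresholds", function(object) {
  cat(sprintf("ScreeningThresholds: leaf >= %g px, substrate >= %g px\n",
              object@leafMin, object@substrateMin))
})

#' ScreeningResult: verdict of the rule-based screen
#'
#' @slot label One of \code{healthy}, \code{unhealthy}, \code{none}.
#' @slot leafArea Measured leaf pixel area.
#' @slot substrateArea Measured substrate pixel area.
#' @export
setClass("ScreeningResult",
  representation(label = "character", leafArea = "numeric",
                 substrateArea = "numeric"),
  validity = function(object) {
    if (!object@label %in% seedlingClasses()) return("unknown label")
    if (object@leafArea < 0 || object@substrateArea < 0)
      return("areas must be nonnegative")
    if (object@label == "none" &&
        (object@leafArea != 0 || object@substrateArea != 0))
      return("label 'none' requires both areas to be zero")
    TRUE
  })

setMethod("show", "ScreeningResult", function(object) {
  cat(sprintf("ScreeningResult: %s (leaf %g px, substrate %g px)\n",
              object@label, object@leafArea, object@substrateArea))
})

#' @describeIn ScreeningResult-class verdict label accessor
#' @param object A \code{ScreeningResult}.
#' @export
setGeneric("screenLabel", function(object) standardGeneric("screenLabel"))

#' @rdname ScreeningResult-class
#' @export
setMethod("screenLabel", "ScreeningResult", function(object) object@label)

#' @describeIn ScreeningResult-class measured areas accessor
#' @export
setGeneric("screenAreas", function(object) standardGeneric("screenAreas"))

#' @rdname ScreeningResult-class
#' @export
setMethod("screenAreas", "ScreeningResult", function(object)
  c(leaf = object@leafArea, substrate = object@substrateArea))

#' ConfusionMatrix3: 3 x 3 predicted-by-true count table
#'
#' Rows are the forecast (predicted) class and columns the true class,
#' both in the fixed order \code{healthy}, \code{unhealthy}, \code{none},
#' so published 3-class confusion tables can be entered verbatim.
#'
#' @slot counts 3 x 3 nonnegative integer matrix.
#' @export
setClass("ConfusionMatrix3", representation(counts = "matrix"),
  validity = function(object) {
    m <- object@counts
    if (!all(dim(m) == c(3L, 3L))) return("counts must be 3 x 3")
    if (any(m < 0)) return("counts must be nonnegative")
    if (any(m != round(m))) return("counts must be integers")
    TRUE
  })

setMethod("show", "ConfusionMatrix3", function(object) {
  cat("ConfusionMatrix3 (rows = predicted, columns = true)\n")
  print(object@counts)
  cat(sprintf("accuracy: %s, misclassified: %d of %d\n",
              formatPercent(overallAccuracy(object)),
              misclassifiedCount(object), sum(object@counts)))
})
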