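#' Shared frame preprocessing
#'
#' Cuts a capture frame into station crops and removes the background of
#' each. Both screening paths (rule-based and network) consume exactly
#' these extracted crops, so their inputs are pixel-identical.
#'
#' @param frame H x W x 3 RGB capture frame.
#' @param stations Number of seedling stations in the frame.
#' @param table Color table, as from \code{\link{colorTable}}.
#' @return List of \linkS4class{SeedlingCrop} objects with extracted
#'   (white-background) images.
#' @export
preprocessFrame <- function(frame, stations = 6L, table = colorTable()) {
  crops <- cropFrame(frame, stations)
  lapply(crops, function(cr)
    new("SeedlingCrop", image = extractSeedling(cropImage(cr), table),
        index = cr@index))
}

#' Screen every station of a capture frame
#'
#' The frame-level pipeline: cut the frame into station crops, extract
#' each seedling, classify each crop with the chosen method and return
#' one verdict per station, left to right. Stations whose label is not
#' \code{healthy} are flagged for removal (an empty station means the
#' pick failed, so it is flagged too).
#'
#' @param frame H x W x 3 RGB capture frame.
#' @param method \code{"physical"} (rule-based area screen) or
#'   \code{"cnn"} (trained network).
#' @param net A trained \linkS4class{SeedlingNet}; required when
#'   \code{method = "cnn"}.
#' @param stations Number of seedling stations (default 6).
#' @param table Color table for extraction and area measurement.
#' @param thresholds \linkS4class{ScreeningThresholds} for the
#'   rule-based screen.
#' @param config Denoising settings from \code{\link{morphologyConfig}}.
#' @param logFile Optional path; one JSON line per verdict is appended,
#'   carrying the station index so downstream replanting logic can
#'   compute trough coordinates.
#' @return Data frame with one row per station: \code{station},
#'   \code{label}, \code{method}, \code{leafArea}, \code{substrateArea}
#'   (rule-based path), per-class score columns (network path) and
#'   \code{removeFlag}.
#' @export
screenFrame <- function(frame, method = c("physical", "cnn"), net = NULL,
                        stations = 6L, table = colorTable(),
                        thresholds = screeningThresholds(),
                        config = morphologyConfig(), logFile = NULL) {
  method <- match.arg(method)
  if (method == "cnn" && is.null(net))
    stop("configuration error: method 'cnn' requires a trained net")
  crops <- preprocessFrame(frame, stations, table)
  rows <- lapply(crops, function(cr) {
    img <- cropImage(cr)
    if (method == "physical") {
      res <- screenPhysical(img, table = table, thresholds = thresholds,
                            config = config)
      data.frame(station = cr@index, label = screenLabel(res),
                 method = method,
                 leafArea = unname(screenAreas(res)["leaf"]),
                 substrateArea = unname(screenAreas(res)["substrate"]),
                 scoreHealthy = NA_real_, scoreUnhealthy = NA_real_,
                 scoreNone = NA_real_, stringsAsFactors = FALSE)
    } else {
      pr <- predictNet(net, resizeForNet(img, net@inputSize))
      data.frame(station = cr@index, label = pr$label, method = method,
                 leafArea = NA_real_, substrateArea = NA_real_,
                 scoreHealthy = unname(pr$scores["healthy"]),
                 scoreUnhealthy = unname(pr$scores["unhealthy"]),
                 scoreNone = unname(pr$scores["none"]),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$removeFlag <- out$label != "healthy"
  if (!is.null(logFile)) {
    con <- file(logFile, open = "a")
    on.exit(close(con))
    for (i in seq_len(nrow(out)))
      writeLines(as.character(jsonlite::toJSON(as.list(out[i, ]),
                                               auto_unbox = TRUE,
                                               digits = NA)), con)
  }
  out
}
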