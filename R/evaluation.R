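#' Build a 3-class confusion matrix from label vectors
#'
#' Tallies predicted-by-true counts over the fixed class order
#' \code{healthy}, \code{unhealthy}, \code{none}. Rows are the forecast
#' class, columns the true class.
#'
#' @param truth Character vector of true labels.
#' @param predicted Character vector of predicted labels (same length).
#' @return A \linkS4class{ConfusionMatrix3}.
#' @export
#' @examples
#' confusionMatrix3(c("healthy", "none"), c("healthy", "none"))
confusionMatrix3 <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  cls <- seedlingClasses()
  bad <- setdiff(unique(c(truth, predicted)), cls)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(predicted, levels = cls),
                  factor(truth, levels = cls))
  m <- matrix(as.integer(counts), 3L, 3L,
              dimnames = list(predicted = cls, true = cls))
  new("ConfusionMatrix3", counts = m)
}

#' Wrap an existing 3 x 3 count matrix
#'
#' For entering published confusion tables directly (rows = forecast,
#' columns = true, class order healthy / unhealthy / none).
#'
#' @param counts 3 x 3 nonnegative integer matrix.
#' @return A \linkS4class{ConfusionMatrix3}.
#' @export
asConfusionMatrix3 <- function(counts) {
  counts <- as.matrix(counts)
  dimnames(counts) <- list(predicted = seedlingClasses(),
                           true = seedlingClasses())
  new("ConfusionMatrix3", counts = counts)
}

#' @describeIn confusionMatrix3 raw count matrix accessor
#' @param object A \code{ConfusionMatrix3}.
#' @export
setGeneric("confusionCounts", function(object)
  standardGeneric("confusionCounts"))

#' @rdname confusionMatrix3
#' @export
setMethod("confusionCounts", "ConfusionMatrix3",
          function(object) object@counts)

#' Per-class TP/FP/FN/TN counts
#'
#' For one class \code{c}: TP is the diagonal entry; FP the rest of the
#' forecast row (negatives predicted positive); FN the rest of the true
#' column (positives predicted negative); TN everything else. The four
#' always sum to the matrix total.
#'
#' @param cm A \linkS4class{ConfusionMatrix3}.
#' @param class Class name or index (1 = healthy, 2 = unhealthy,
#'   3 = none).
#' @return Named numeric vector \code{c(TP, FP, FN, TN)}.
#' @export
perClassCounts <- function(cm, class) {
  stopifnot(is(cm, "ConfusionMatrix3"))
  if (is.character(class)) class <- match(class, seedlingClasses())
  if (is.na(class) || class < 1L || class > 3L) stop("unknown class")
  m <- cm@counts
  tp <- m[class, class]
  fp <- sum(m[class, ]) - tp
  fn <- sum(m[, class]) - tp
  tn <- sum(m) - tp - fp - fn
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' Precision, recall and F1 from TP/FP/FN/TN counts
#'
#' precision = TP / (TP + FP), recall = TP / (TP + FN), F1 their harmonic
#' mean. A zero denominator yields 0 for the affected metric with the
#' \code{degenerate} flag set (so batch reports never abort on empty
#' classes).
#'
#' @param counts Named vector with elements \code{TP}, \code{FP},
#'   \code{FN} (as from \code{\link{perClassCounts}}).
#' @return List with \code{precision}, \code{recall}, \code{f1} (each in
#'   [0, 1]) and logical \code{degenerate}.
#' @export
#' @examples
#' classMetrics(c(TP = 439, FP = 11, FN = 12, TN = 438))
classMetrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  degenerate <- FALSE
  if (tp + fp == 0) { precision <- 0; degenerate <- TRUE }
  else precision <- tp / (tp + fp)
  if (tp + fn == 0) { recall <- 0; degenerate <- TRUE }
  else recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       degenerate = degenerate)
}

#' Overall accuracy of a confusion matrix
#'
#' Trace over total: the fraction of samples whose forecast equals the
#' truth.
#'
#' @param cm A \linkS4class{ConfusionMatrix3}.
#' @return Accuracy in [0, 1].
#' @export
overallAccuracy <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix3"))
  total <- sum(cm@counts)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm@counts)) / total
}

#' Number of misclassified samples
#'
#' Sum of the off-diagonal entries.
#'
#' @param cm A \linkS4class{ConfusionMatrix3}.
#' @return Nonnegative integer count.
#' @export
misclassifiedCount <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix3"))
  as.integer(sum(cm@counts) - sum(diag(cm@counts)))
}

#' Full evaluation report for a confusion matrix
#'
#' Per-class TP/FP/FN/TN, precision/recall/F1 and overall accuracy in one
#' data frame, matching how 3-class screening results are usually
#' tabulated.
#'
#' @param cm A \linkS4class{ConfusionMatrix3}.
#' @return Data frame with one row per class.
#' @export
metricsTable <- function(cm) {
  rows <- lapply(seedlingClasses(), function(cl) {
    cc <- perClassCounts(cm, cl)
    m <- classMetrics(cc)
    data.frame(class = cl, TP = cc[["TP"]], FP = cc[["FP"]],
               FN = cc[["FN"]], TN = cc[["TN"]],
               precision = m$precision, recall = m$recall, f1 = m$f1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "accuracy") <- overallAccuracy(cm)
  attr(out, "misclassified") <- misclassifiedCount(cm)
  out
}

#' Render a fraction as a percentage string
#'
#' Rounds half away from zero at two decimals and strips trailing zeros,
#' the convention used in screening reports (0.9744 -> "97.44%", 0.92 ->
#' "92%", 0.974 -> "97.4%").
#'
#' @param x Fraction in [0, 1].
#' @return Character percentage.
#' @export
formatPercent <- function(x) {
  v <- roundHalfUp(x * 10000) / 100
  s <- formatC(v, format = "f", digits = 2)
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  paste0(s, "%")
}
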