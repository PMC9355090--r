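# Shared fixtures and independent oracles used across the test files.

# uniform-color H x W x 3 image
solidImg <- function(h, w, rgb) {
  array(rep(as.numeric(rgb), each = h * w), dim = c(h, w, 3L))
}

randomMask <- function(h, w, p = 0.4) {
  matrix(sample(c(0, 255), h * w, replace = TRUE, prob = c(1 - p, p)), h, w)
}

# Brute-force binary dilation/erosion with a 3x3 diamond (cross) element:
# the independent morphology oracle.
bruteDilate <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  out <- matrix(0, h, w)
  for (r in seq_len(h))
    for (c in seq_len(w))
      out[r, c] <- max(pad[r + 1L, c + 1L], pad[r, c + 1L],
                       pad[r + 2L, c + 1L], pad[r + 1L, c],
                       pad[r + 1L, c + 2L])
  out
}

bruteErode <- function(mask) {
  255 - bruteDilate(255 - mask)
}

# Brute-force per-class precision/recall/F1 straight from label vectors:
# the independent metrics oracle.
bruteClassMetrics <- function(truth, pred, cls) {
  tp <- sum(pred == cls & truth == cls)
  fp <- sum(pred == cls & truth != cls)
  fn <- sum(pred != cls & truth == cls)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

# Published 900-sample confusion tables (rows = forecast, cols = true,
# class order healthy / unhealthy / none), used as fixtures.
dlConfusion <- function() asConfusionMatrix3(
  matrix(c(439, 12, 0,
           11, 138, 0,
           0, 0, 300), nrow = 3L))

physConfusion <- function() asConfusionMatrix3(
  matrix(c(399, 55, 0,
           41, 105, 0,
           0, 0, 300), nrow = 3L))

# one small manifest with every class represented
tinyManifest <- function(n = 10L) {
  data.frame(path = sprintf("img%03d.png", seq_len(3L * n)),
             label = rep(seedlingClasses(), each = n),
             stringsAsFactors = FALSE)
}
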