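#' SeedlingNet: a residual convolutional classifier
#'
#' Container for the network architecture (layer spec), its parameters,
#' batch-normalisation running statistics and training history. Networks
#' are built with \code{\link{buildTransferNet}} or
#' \code{\link{buildCustomNet}} and trained with \code{\link{trainNet}}.
#'
#' @slot arch Architecture name ("transfer" or "custom").
#' @slot spec Layer specification consumed by the compiled engine.
#' @slot shapes Parameter shape registry (used for init and counting).
#' @slot params List of parameter arrays.
#' @slot state Batch-norm running means/variances.
#' @slot inputSize Square input side length (pixels).
#' @slot nClasses Number of output classes.
#' @slot classes Class labels in encoding order.
#' @slot history Training history (per-epoch metrics, per-step losses).
#' @slot trained Whether \code{trainNet} has been run.
#' @export
setClass("SeedlingNet",
  representation(arch = "character", spec = "list", shapes = "list",
                 params = "list", state = "list", inputSize = "integer",
                 nClasses = "integer", classes = "character",
                 history = "list", trained = "logical"))

setMethod("show", "SeedlingNet", function(object) {
  cat(sprintf("SeedlingNet '%s': %d x %d x 3 input, %d classes, %s parameters%s\n",
              object@arch, object@inputSize, object@inputSize,
              object@nClasses,
              format(nParams(object), big.mark = ","),
              if (object@trained) " (trained)" else ""))
  if (!is.null(object@spec$stageOut))
    cat("stage output sizes:",
        paste(object@spec$stageOut, collapse = ", "), "\n")
})

# ---- spec construction ----------------------------------------------------

.sizeAfter <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# Assemble a plain residual classification network: a conv/bn/relu stem
# (optionally max-pooled), stages of two-conv residual blocks with
# projection shortcuts on channel or stride change, global average
# pooling and a fully connected head. Convolutions are bias-free; batch
# norm provides the affine terms.
.buildResidualNet <- function(arch, inputSize, nClasses, stem, stageC,
                              stageStride, blocksPerStage = 2L) {
  layers <- list()
  shapes <- list()
  pidx <- 0L
  addConv <- function(k, stride, pad, inC, outC) {
    pidx <<- pidx + 1L
    shapes[[pidx]] <<- list(kind = "conv", outC = outC,
                            cols = inC * k * k)
    layers[[length(layers) + 1L]] <<- list(type = "conv", k = k,
      stride = stride, pad = pad, inC = inC, outC = outC, pidx = pidx)
    pidx
  }
  addBn <- function(C) {
    pidx <<- pidx + 1L
    shapes[[pidx]] <<- list(kind = "bn", C = C)
    layers[[length(layers) + 1L]] <<- list(type = "bn", C = C, pidx = pidx)
    pidx
  }
  addPlain <- function(type, ...)
    layers[[length(layers) + 1L]] <<- list(type = type, ...)

  size <- inputSize
  addConv(stem$k, stem$stride, stem$pad, 3L, stem$C)
  addBn(stem$C)
  addPlain("relu")
  size <- .sizeAfter(size, stem$k, stem$stride, stem$pad)
  if (isTRUE(stem$pool)) {
    addPlain("maxpool", k = 3L, stride = 2L, pad = 1L)
    size <- .sizeAfter(size, 3L, 2L, 1L)
  }

  inC <- stem$C
  stageOut <- integer(0)
  for (si in seq_along(stageC)) {
    outC <- stageC[si]
    for (bi in seq_len(blocksPerStage)) {
      stride <- if (bi == 1L) stageStride[si] else 1L
      proj <- stride != 1L || inC != outC
      if (proj) {
        # projection shortcut: 1x1 conv (registered before the block) + bn
        pidx <- pidx + 1L
        cp <- pidx
        shapes[[cp]] <- list(kind = "conv", outC = outC, cols = inC)
        pidx <- pidx + 1L
        bp <- pidx
        shapes[[bp]] <- list(kind = "bn", C = outC)
        addPlain("block_start", proj = TRUE, stride = stride,
                 convPidx = cp, bnPidx = bp)
      } else {
        addPlain("block_start", proj = FALSE)
      }
      addConv(3L, stride, 1L, inC, outC)
      addBn(outC)
      addPlain("relu")
      addConv(3L, 1L, 1L, outC, outC)
      addBn(outC)
      addPlain("block_add")
      if (bi == 1L) size <- .sizeAfter(size, 3L, stride, 1L)
      inC <- outC
    }
    stageOut <- c(stageOut, size)
  }
  addPlain("gap")
  pidx <- pidx + 1L
  shapes[[pidx]] <- list(kind = "fc", outF = nClasses, inF = inC)
  addPlain("fc", inF = inC, outF = nClasses, pidx = pidx)

  spec <- list(input = c(inputSize, inputSize, 3L), layers = layers,
               stageOut = stageOut, featureWidth = inC)
  new("SeedlingNet", arch = arch, spec = spec, shapes = shapes,
      params = .initNetParams(shapes), state = .initNetState(shapes),
      inputSize = as.integer(inputSize), nClasses = as.integer(nClasses),
      classes = seedlingClasses(), history = list(), trained = FALSE)
}

# He-style initialisation for convolutions and the head; unit gamma and
# zero beta for batch norm. Draws from the current R RNG stream.
.initNetParams <- function(shapes) {
  lapply(shapes, function(s) {
    switch(s$kind,
      conv = matrix(stats::rnorm(s$outC * s$cols, sd = sqrt(2 / s$cols)),
                    nrow = s$outC, ncol = s$cols),
      bn = list(gamma = rep(1, s$C), beta = rep(0, s$C)),
      fc = list(W = matrix(stats::rnorm(s$outF * s$inF,
                                        sd = sqrt(2 / s$inF)),
                           nrow = s$outF, ncol = s$inF),
                b = rep(0, s$outF)))
  })
}

.initNetState <- function(shapes) {
  lapply(shapes, function(s) {
    if (s$kind == "bn") list(mean = rep(0, s$C), var = rep(1, s$C), n = 0)
    else NULL
  })
}

#' Build the 18-layer residual transfer network
#'
#' The standard batch-normalised 18-layer residual classification
#' backbone (7x7 stride-2 stem with 3x3 max pooling, four stages of two
#' residual blocks with 64/128/256/512 channels, bias-free convolutions,
#' projection shortcuts on downsampling) with its original 1000-way head
#' replaced by a fully connected 3-way head, giving 11,178,051 trainable
#' parameters. Weights are randomly initialised from the current RNG
#' stream; for transfer learning, load pretrained backbone weights into
#' \code{@params} before fine-tuning.
#'
#' @param inputSize Square input side length (default 224).
#' @param nClasses Number of output classes (default 3).
#' @return A \linkS4class{SeedlingNet}.
#' @export
#' @examples
#' net <- buildTransferNet()
#' nParams(net)  # 11178051
buildTransferNet <- function(inputSize = 224L, nClasses = 3L) {
  .buildResidualNet("transfer", inputSize, nClasses,
                    stem = list(k = 7L, stride = 2L, pad = 3L, C = 64L,
                                pool = TRUE),
                    stageC = c(64L, 128L, 256L, 512L),
                    stageStride = c(1L, 2L, 2L, 2L))
}

#' Build the compact custom residual network
#'
#' A narrower 18-layer-style residual network sized for 224 x 224 inputs:
#' a 3x3 stride-3 stem (no pooling) and five stages of two residual
#' blocks with 16/32/64/128/256 channels. Stage strides (1, 3, 3, 2, 2)
#' are chosen so the per-stage spatial output sizes are 74, 25, 9, 5 and
#' 3 pixels, followed by global average pooling and a 3-way head.
#'
#' @inheritParams buildTransferNet
#' @return A \linkS4class{SeedlingNet}.
#' @export
#' @examples
#' net <- buildCustomNet()
#' stageOutputSizes(net)  # 74 25 9 5 3
buildCustomNet <- function(inputSize = 224L, nClasses = 3L) {
  .buildResidualNet("custom", inputSize, nClasses,
                    stem = list(k = 3L, stride = 3L, pad = 0L, C = 16L,
                                pool = FALSE),
                    stageC = c(16L, 32L, 64L, 128L, 256L),
                    stageStride = c(1L, 3L, 3L, 2L, 2L))
}

#' @describeIn buildTransferNet total trainable parameter count
#' @param object A \code{SeedlingNet}.
#' @export
setGeneric("nParams", function(object) standardGeneric("nParams"))

#' @rdname buildTransferNet
#' @export
setMethod("nParams", "SeedlingNet", function(object) {
  sum(vapply(object@params, function(p) {
    if (is.list(p)) sum(lengths(p)) else length(p)
  }, numeric(1L)))
})

#' @describeIn buildCustomNet spatial output size after each stage
#' @param object A \code{SeedlingNet}.
#' @export
setGeneric("stageOutputSizes", function(object)
  standardGeneric("stageOutputSizes"))

#' @rdname buildCustomNet
#' @export
setMethod("stageOutputSizes", "SeedlingNet",
          function(object) object@spec$stageOut)

# ---- forward / parameter plumbing -----------------------------------------

# Scale 8-bit images into the network's input range.
.preprocessTensor <- function(x) x / 255 - 0.5

# Run the engine. x: (H, W, 3, N) array already preprocessed.
.netRun <- function(net, x, labels = integer(0), training = FALSE,
                    grad = FALSE, bnMomentum = 0.1) {
  seednetRun(net@spec, net@params, net@state, x, as.integer(labels),
             training, grad, bnMomentum)
}

.flattenParams <- function(params) unlist(params, use.names = FALSE)

.unflattenParams <- function(vec, template) {
  pos <- 0L
  walk <- function(t) {
    if (is.list(t)) return(lapply(t, walk))
    n <- length(t)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(t))) dim(out) <- dim(t)
    out
  }
  out <- walk(template)
  stopifnot(pos == length(vec))
  out
}

#' Load a batch of images as a network input tensor
#'
#' Reads each image, optionally removes its background (the protocol the
#' classifier is meant for: white-background extracted seedlings), resizes
#' it to the network input size and stacks the results into an
#' (size, size, 3, N) array of 8-bit values.
#'
#' @param paths Character vector of image paths.
#' @param size Square side length (e.g. \code{net@inputSize}).
#' @param extract Apply \code{\link{extractSeedling}} before resizing.
#' @param table Color table used when \code{extract = TRUE}.
#' @return Numeric array (size, size, 3, N), values in [0, 255].
#' @export
loadImageBatch <- function(paths, size = 224L, extract = FALSE,
                           table = colorTable()) {
  n <- length(paths)
  x <- array(0, dim = c(size, size, 3L, n))
  for (i in seq_len(n)) {
    img <- readImageRGB(paths[i])
    if (extract) img <- extractSeedling(img, table)
    x[, , , i] <- resizeForNet(img, size)
  }
  x
}

#' Training configuration
#'
#' Hyperparameters for \code{\link{trainNet}}: cross-entropy loss with
#' the Adam optimiser. The mini-batch size defaults to 32; learning rates
#' of 1e-3 down to 1e-5 and 20--30 epochs are the ranges worth sweeping
#' for this problem (smaller rates give visibly smoother loss curves).
#' All randomness (weight init, shuffling) derives from \code{seed}.
#'
#' @param learningRate Adam step size.
#' @param epochs Number of passes over the training split.
#' @param batchSize Mini-batch size.
#' @param seed Integer seed controlling every RNG draw in training.
#' @param reinitWeights Re-initialise weights from \code{seed} before
#'   training (set \code{FALSE} to fine-tune existing weights).
#' @param shuffle Reshuffle the training split each epoch.
#' @param bnMomentum Batch-norm running-statistics momentum: 0 (the
#'   default) keeps cumulative averages of the per-batch statistics,
#'   which are well calibrated even after few optimiser steps; a
#'   positive value switches to the exponential moving average common
#'   for long training runs.
#' @return Named list of settings.
#' @export
trainingConfig <- function(learningRate = 1e-3, epochs = 20L,
                           batchSize = 32L, seed = 1L,
                           reinitWeights = TRUE, shuffle = TRUE,
                           bnMomentum = 0) {
  stopifnot(learningRate >= 0, epochs >= 1, batchSize >= 1)
  list(learningRate = learningRate, epochs = as.integer(epochs),
       batchSize = as.integer(batchSize), seed = as.integer(seed),
       reinitWeights = isTRUE(reinitWeights), shuffle = isTRUE(shuffle),
       bnMomentum = bnMomentum)
}

#' Train a seedling classification network
#'
#' Minimises softmax cross-entropy with Adam over the manifest's
#' \code{train} split, evaluating the \code{val} split after every epoch.
#' The parameters of the epoch with the highest validation accuracy
#' (ties broken by lower validation loss) are kept as the final model.
#' Training aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param net A \linkS4class{SeedlingNet}.
#' @param manifest Data frame with columns \code{path}, \code{label},
#'   \code{split} (as from \code{\link{splitDataset}} or
#'   \code{\link{generateDataset}}).
#' @param config Settings from \code{\link{trainingConfig}}.
#' @param tensors Optional precomputed list with elements \code{x}
#'   ((H, W, 3, N) array, 0--255) and \code{y} (integer labels) aligned
#'   with \code{manifest}; when omitted the images are loaded from
#'   \code{manifest$path}.
#' @param verbose Print per-epoch metrics.
#' @return The trained \linkS4class{SeedlingNet}; \code{@history} holds
#'   \code{epochs} (per-epoch loss/accuracy data frame) and
#'   \code{stepLoss} (loss after every optimiser step).
#' @export
trainNet <- function(net, manifest, config = trainingConfig(),
                     tensors = NULL, verbose = FALSE) {
  stopifnot(is(net, "SeedlingNet"))
  cls <- net@classes
  if (!all(c("path", "label", "split") %in% names(manifest)) &&
      is.null(tensors))
    stop("manifest must have columns path, label, split")
  trainIdx <- which(manifest$split == "train")
  valIdx <- which(manifest$split == "val")
  if (!all(cls %in% manifest$label[trainIdx]))
    stop("train split must contain every class")

  set.seed(config$seed)
  if (config$reinitWeights) {
    net@params <- .initNetParams(net@shapes)
    net@state <- .initNetState(net@shapes)
  }

  if (is.null(tensors)) {
    tensors <- list(x = loadImageBatch(manifest$path, net@inputSize),
                    y = match(manifest$label, cls))
  }
  x <- .preprocessTensor(tensors$x)
  y <- tensors$y

  flat <- .flattenParams(net@params)
  mAdam <- vAdam <- numeric(length(flat))
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  tStep <- 0L
  stepLoss <- numeric(0)
  epochRows <- list()
  best <- list(acc = -Inf, loss = Inf, params = net@params,
               state = net@state)

  evalSplit <- function(idx) {
    if (!length(idx)) return(c(NA_real_, NA_real_))
    tot <- 0; correct <- 0; lossSum <- 0
    for (b in split(idx, ceiling(seq_along(idx) / 64))) {
      r <- .netRun(net, x[, , , b, drop = FALSE], y[b], training = FALSE)
      pred <- max.col(t(r$logits), ties.method = "first")
      correct <- correct + sum(pred == y[b])
      lossSum <- lossSum + r$loss * length(b)
      tot <- tot + length(b)
    }
    c(lossSum / tot, correct / tot)
  }

  for (ep in seq_len(config$epochs)) {
    idx <- if (config$shuffle) sample(trainIdx) else trainIdx
    batches <- split(idx, ceiling(seq_along(idx) / config$batchSize))
    epLoss <- 0; epCorrect <- 0
    for (b in batches) {
      r <- .netRun(net, x[, , , b, drop = FALSE], y[b], training = TRUE,
                   grad = TRUE, bnMomentum = config$bnMomentum)
      if (!is.finite(r$loss))
        stop("training diverged: non-finite loss at epoch ", ep,
             " (learning rate ", config$learningRate, ")")
      net@state <- r$state
      g <- .flattenParams(r$grads)
      tStep <- tStep + 1L
      mAdam <- b1 * mAdam + (1 - b1) * g
      vAdam <- b2 * vAdam + (1 - b2) * g * g
      mhat <- mAdam / (1 - b1^tStep)
      vhat <- vAdam / (1 - b2^tStep)
      flat <- flat - config$learningRate * mhat / (sqrt(vhat) + epsA)
      net@params <- .unflattenParams(flat, net@params)
      stepLoss <- c(stepLoss, r$loss)
      pred <- max.col(t(r$logits), ties.method = "first")
      epCorrect <- epCorrect + sum(pred == y[b])
      epLoss <- epLoss + r$loss * length(b)
    }
    # recalibrate the batch-norm running statistics with the epoch's
    # final weights (a gradient-free pass over the training split), so
    # inference-mode evaluation reflects the weights actually kept
    net@state <- .initNetState(net@shapes)
    for (b in batches) {
      r <- .netRun(net, x[, , , b, drop = FALSE], training = TRUE,
                   bnMomentum = 0)
      net@state <- r$state
    }
    val <- evalSplit(valIdx)
    epochRows[[ep]] <- data.frame(
      epoch = ep, trainLoss = epLoss / length(trainIdx),
      trainAcc = epCorrect / length(trainIdx),
      valLoss = val[1L], valAcc = val[2L])
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f acc %.4f | val loss %s acc %s",
                      ep, epochRows[[ep]]$trainLoss, epochRows[[ep]]$trainAcc,
                      format(val[1L]), format(val[2L])))
    selAcc <- if (is.na(val[2L])) epochRows[[ep]]$trainAcc else val[2L]
    selLoss <- if (is.na(val[1L])) epochRows[[ep]]$trainLoss else val[1L]
    if (selAcc > best$acc || (selAcc == best$acc && selLoss < best$loss)) {
      best <- list(acc = selAcc, loss = selLoss, params = net@params,
                   state = net@state)
    }
  }
  net@params <- best$params
  net@state <- best$state
  net@history <- list(epochs = do.call(rbind, epochRows),
                      stepLoss = stepLoss)
  net@trained <- TRUE
  net
}

#' Classify a single image
#'
#' Runs the network in inference mode and returns the argmax class with
#' normalised class scores. Tied logits resolve to the lowest class
#' index (healthy before unhealthy before none).
#'
#' @param net A \linkS4class{SeedlingNet}.
#' @param image RGB array whose height and width equal
#'   \code{net@inputSize} (resize with \code{\link{resizeForNet}}).
#' @return List with \code{label} and named \code{scores} summing to 1.
#' @export
predictNet <- function(net, image) {
  stopifnot(is(net, "SeedlingNet"))
  checkImageRGB(image)
  d <- dim(image)
  if (d[1L] != net@inputSize || d[2L] != net@inputSize)
    stop("image must be ", net@inputSize, " x ", net@inputSize,
         "; got ", d[1L], " x ", d[2L])
  x <- array(.preprocessTensor(image), dim = c(d[1L], d[2L], 3L, 1L))
  r <- .netRun(net, x, training = FALSE)
  scores <- drop(r$probs)
  names(scores) <- net@classes
  list(label = net@classes[which.max(drop(r$logits))], scores = scores)
}

#' Classify a batch of images
#'
#' @param net A \linkS4class{SeedlingNet}.
#' @param x (size, size, 3, N) array of 8-bit images (as from
#'   \code{\link{loadImageBatch}}).
#' @return Data frame with \code{label} and one score column per class.
#' @export
predictBatch <- function(net, x) {
  stopifnot(is(net, "SeedlingNet"))
  labels <- character(0)
  scores <- NULL
  idx <- seq_len(dim(x)[4L])
  for (b in split(idx, ceiling(seq_along(idx) / 64))) {
    r <- .netRun(net, .preprocessTensor(x[, , , b, drop = FALSE]),
                 training = FALSE)
    labels <- c(labels,
                net@classes[max.col(t(r$logits), ties.method = "first")])
    scores <- rbind(scores, t(r$probs))
  }
  out <- data.frame(label = labels, stringsAsFactors = FALSE)
  colnames(scores) <- net@classes
  cbind(out, as.data.frame(scores))
}

#' Save / load a trained network
#'
#' Serialises the full \linkS4class{SeedlingNet} (spec, parameters,
#' running statistics, history) to an RDS file.
#'
#' @param net A \linkS4class{SeedlingNet}.
#' @param path Destination file.
#' @return \code{path} (for \code{saveNet}); the network (for
#'   \code{loadNet}).
#' @export
saveNet <- function(net, path) {
  saveRDS(net, path)
  invisible(path)
}

#' @rdname saveNet
#' @export
loadNet <- function(path) {
  net <- readRDS(path)
  stopifnot(is(net, "SeedlingNet"))
  net
}
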