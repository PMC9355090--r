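test_that("the transfer network has the exact published architecture", {
  net <- buildTransferNet()
  expect_identical(nParams(net), 11178051)
  # 3-way head on the 512-wide backbone feature
  fc <- net@params[[length(net@params)]]
  expect_equal(dim(fc$W), c(3L, 512L))
  expect_equal(length(fc$b), 3L)
  set.seed(41)
  img <- array(sample(0:255, 224 * 224 * 3, TRUE), dim = c(224, 224, 3))
  p <- predictNet(net, img)
  expect_length(p$scores, 3L)
  expect_true(all(is.finite(p$scores)))
  expect_equal(sum(p$scores), 1)
})

test_that("the custom network reproduces the per-stage output sizes", {
  net <- buildCustomNet()
  expect_equal(stageOutputSizes(net), c(74L, 25L, 9L, 5L, 3L))
  fc <- net@params[[length(net@params)]]
  expect_equal(nrow(fc$W), 3L)  # 3-way classification head
  set.seed(42)
  img <- array(sample(0:255, 224 * 224 * 3, TRUE), dim = c(224, 224, 3))
  p <- predictNet(net, img)
  expect_true(all(is.finite(p$scores)))
  expect_length(p$scores, 3L)
})

test_that("engine gradients match finite differences on a small net", {
  set.seed(43)
  tiny <- SeedlingScreen:::.buildResidualNet("custom", 12L, 3L,
    stem = list(k = 3L, stride = 1L, pad = 1L, C = 4L, pool = FALSE),
    stageC = c(4L, 6L), stageStride = c(1L, 2L))
  x <- array(rnorm(12 * 12 * 3 * 2), dim = c(12, 12, 3, 2))
  y <- c(1L, 3L)
  run <- function(params, grad)
    SeedlingScreen:::seednetRun(tiny@spec, params, tiny@state, x, y,
                                TRUE, grad, 0.1)
  g <- SeedlingScreen:::.flattenParams(run(tiny@params, TRUE)$grads)
  flat <- SeedlingScreen:::.flattenParams(tiny@params)
  idx <- sample(length(flat), 40)
  eps <- 1e-6
  num <- vapply(idx, function(i) {
    up <- flat; up[i] <- up[i] + eps
    dn <- flat; dn[i] <- dn[i] - eps
    (run(SeedlingScreen:::.unflattenParams(up, tiny@params), FALSE)$loss -
     run(SeedlingScreen:::.unflattenParams(dn, tiny@params), FALSE)$loss) /
      (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - g[idx])), 1e-5)
})

test_that("training fits a separable three-class problem", {
  # solid-color classes with noise are linearly separable after pooling
  set.seed(44)
  n <- 12L  # per class
  mkimg <- function(rgb) pmin(255, pmax(0,
    solidImg(16, 16, rgb) + array(rnorm(16 * 16 * 3, 0, 12),
                                  dim = c(16, 16, 3))))
  x <- array(0, dim = c(16, 16, 3, 3 * n))
  y <- rep(1:3, each = n)
  protos <- list(c(40, 170, 60), c(120, 70, 40), c(235, 235, 235))
  for (i in seq_len(3 * n)) x[, , , i] <- mkimg(protos[[y[i]]])
  man <- data.frame(label = seedlingClasses()[y],
                    split = rep("train", 3 * n))
  net <- buildCustomNet(inputSize = 16L)
  net <- trainNet(net, man, trainingConfig(learningRate = 1e-3,
                                           epochs = 30, seed = 5),
                  tensors = list(x = x, y = y))
  hist <- net@history$epochs
  expect_gte(max(hist$trainAcc), 0.99)
  expect_true(net@trained)
})

test_that("a zero learning rate freezes training", {
  set.seed(45)
  x <- array(sample(0:255, 12 * 12 * 3 * 9, TRUE), dim = c(12, 12, 3, 9))
  y <- rep(1:3, each = 3)
  man <- data.frame(label = seedlingClasses()[y], split = "train")
  net <- buildCustomNet(inputSize = 12L)
  net <- trainNet(net, man,
                  trainingConfig(learningRate = 0, epochs = 4, seed = 6,
                                 shuffle = FALSE),
                  tensors = list(x = x, y = y))
  expect_equal(diff(range(net@history$epochs$trainLoss)), 0)
})

test_that("smaller learning rates give smoother loss curves", {
  set.seed(46)
  n <- 10L
  x <- array(0, dim = c(16, 16, 3, 3 * n))
  y <- rep(1:3, each = n)
  protos <- list(c(40, 170, 60), c(120, 70, 40), c(235, 235, 235))
  for (i in seq_len(3 * n))
    x[, , , i] <- pmin(255, pmax(0, solidImg(16, 16, protos[[y[i]]]) +
      array(rnorm(16 * 16 * 3, 0, 15), dim = c(16, 16, 3))))
  man <- data.frame(label = seedlingClasses()[y], split = "train")
  roughness <- function(lr) {
    net <- trainNet(buildCustomNet(inputSize = 16L), man,
                    trainingConfig(learningRate = lr, epochs = 10,
                                   batchSize = 10, seed = 7),
                    tensors = list(x = x, y = y))
    d <- diff(net@history$stepLoss)
    sum(diff(sign(d[d != 0])) != 0)
  }
  expect_lt(roughness(1e-5), roughness(1e-3))
})

test_that("prediction normalises scores, breaks ties low and checks size", {
  net <- buildCustomNet(inputSize = 16L)
  # force tied logits: zero head weights and equal biases
  k <- length(net@params)
  net@params[[k]]$W[] <- 0
  net@params[[k]]$b[] <- 0.5
  img <- solidImg(16, 16, c(100, 100, 100))
  p <- predictNet(net, img)
  expect_equal(p$label, "healthy")  # lowest class index wins ties
  expect_equal(sum(p$scores), 1)
  expect_error(predictNet(net, solidImg(20, 20, c(1, 1, 1))), "16 x 16")
})

test_that("networks round-trip through saveNet/loadNet", {
  net <- buildCustomNet(inputSize = 12L)
  path <- tempfile(fileext = ".rds")
  saveNet(net, path)
  net2 <- loadNet(path)
  expect_equal(net2@params, net@params)
  img <- solidImg(12, 12, c(50, 120, 80))
  expect_equal(predictNet(net2, img), predictNet(net, img))
})
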