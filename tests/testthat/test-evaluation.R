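test_that("confusionMatrix3 tallies predicted-by-true counts", {
  cm <- confusionMatrix3(c("healthy", "unhealthy", "none"),
                         c("healthy", "unhealthy", "none"))
  expect_equal(unname(diag(confusionCounts(cm))), c(1, 1, 1))
  expect_equal(misclassifiedCount(cm), 0L)

  cm2 <- confusionMatrix3(rep(seedlingClasses(), times = c(2, 3, 4)),
                          rep("healthy", 9))
  expect_equal(unname(rowSums(confusionCounts(cm2))), c(9, 0, 0))
  expect_error(confusionMatrix3("healthy", "weird"), "unknown label")
  expect_error(confusionMatrix3(c("healthy", "none"), "healthy"),
               "equal length")
})

test_that("per-class counts decompose the matrix and sum to the total", {
  cm <- dlConfusion()
  expect_equal(perClassCounts(cm, "healthy"),
               c(TP = 439, FP = 11, FN = 12, TN = 438))
  expect_equal(perClassCounts(cm, "unhealthy"),
               c(TP = 138, FP = 12, FN = 11, TN = 739))
  expect_equal(perClassCounts(cm, "none"),
               c(TP = 300, FP = 0, FN = 0, TN = 600))
  pm <- physConfusion()
  expect_equal(perClassCounts(pm, "healthy"),
               c(TP = 399, FP = 41, FN = 55, TN = 405))
  expect_equal(perClassCounts(pm, "unhealthy"),
               c(TP = 105, FP = 55, FN = 41, TN = 699))
  for (cm_ in list(cm, pm))
    for (cl in seedlingClasses())
      expect_equal(sum(perClassCounts(cm_, cl)), sum(confusionCounts(cm_)))
})

test_that("classMetrics computes precision, recall and F1 with safe zeros", {
  m <- classMetrics(c(TP = 439, FP = 11, FN = 12, TN = 438))
  expect_equal(m$precision, 439 / 450)
  expect_equal(m$recall, 439 / 451)
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  expect_false(m$degenerate)

  perfect <- classMetrics(c(TP = 300, FP = 0, FN = 0, TN = 600))
  expect_equal(unlist(perfect[c("precision", "recall", "f1")]),
               c(precision = 1, recall = 1, f1 = 1))

  degen <- classMetrics(c(TP = 0, FP = 0, FN = 0, TN = 10))
  expect_equal(degen$precision, 0)
  expect_equal(degen$recall, 0)
  expect_equal(degen$f1, 0)
  expect_true(degen$degenerate)
})

test_that("metrics agree with brute-force recomputation from labels", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    truth <- sample(seedlingClasses(), n, replace = TRUE)
    pred <- sample(seedlingClasses(), n, replace = TRUE)
    cm <- confusionMatrix3(truth, pred)
    for (cl in seedlingClasses()) {
      mine <- classMetrics(perClassCounts(cm, cl))
      ref <- bruteClassMetrics(truth, pred, cl)
      expect_equal(mine$precision, ref$precision)
      expect_equal(mine$recall, ref$recall)
      expect_equal(mine$f1, ref$f1)
    }
    expect_equal(overallAccuracy(cm), mean(truth == pred))
    expect_equal(misclassifiedCount(cm), sum(truth != pred))
  }
})

test_that("micro-averaged recall equals accuracy", {
  set.seed(32)
  for (i in 1:20) {
    cm <- asConfusionMatrix3(matrix(sample(0:50, 9, TRUE), 3, 3))
    counts <- lapply(seedlingClasses(), function(cl) perClassCounts(cm, cl))
    tp <- sum(vapply(counts, `[[`, numeric(1), "TP"))
    fn <- sum(vapply(counts, `[[`, numeric(1), "FN"))
    expect_equal(tp / (tp + fn), overallAccuracy(cm))
  }
})

test_that("accuracy and misclassification handle edge cases", {
  expect_equal(overallAccuracy(dlConfusion()), 877 / 900)
  expect_equal(misclassifiedCount(dlConfusion()), 23L)
  expect_equal(overallAccuracy(physConfusion()), 804 / 900)
  expect_equal(misclassifiedCount(physConfusion()), 96L)
  perfect <- asConfusionMatrix3(diag(c(5, 6, 7)))
  expect_equal(overallAccuracy(perfect), 1)
  expect_error(overallAccuracy(asConfusionMatrix3(matrix(0, 3, 3))),
               "empty")
})

test_that("percent rendering matches the reporting convention", {
  expect_equal(formatPercent(0.9744), "97.44%")
  expect_equal(formatPercent(0.92), "92%")
  expect_equal(formatPercent(0.974), "97.4%")
  expect_equal(formatPercent(1), "100%")
  expect_equal(formatPercent(0), "0%")
  expect_equal(formatPercent(0.92615), "92.62%")  # half away from zero
})

test_that("metricsTable assembles the full report", {
  tab <- metricsTable(dlConfusion())
  expect_equal(tab$class, seedlingClasses())
  expect_equal(attr(tab, "accuracy"), 877 / 900)
  expect_equal(attr(tab, "misclassified"), 23L)
  expect_equal(tab$TP, c(439, 138, 300))
})
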