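test_that("renderSeedling hits the target areas exactly and labels by rule", {
  blank <- renderSeedling(synthParams(frameWidth = 100L, frameHeight = 80L,
                                      leafBlobCount = 0L, targetLeafArea = 0,
                                      targetSubstrateArea = 0, seed = 1))
  expect_equal(blank$record$label, "none")
  expect_equal(blank$record$leafArea, 0)
  expect_equal(blank$record$substrateArea, 0)
  expect_true(all(blank$image >= 221))  # background stays in the white range

  healthy <- renderSeedling(synthParams(leafBlobCount = 3L,
                                        targetLeafArea = 3000,
                                        targetSubstrateArea = 1500,
                                        seed = 2))
  expect_equal(healthy$record$label, "healthy")
  expect_equal(healthy$record$leafArea, 3000)       # exact, so within 5%
  expect_equal(healthy$record$substrateArea, 1500)

  thin <- renderSeedling(synthParams(leafBlobCount = 3L,
                                     targetLeafArea = 1000,
                                     targetSubstrateArea = 1500, seed = 3))
  expect_equal(thin$record$label, "unhealthy")

  fewBlobs <- renderSeedling(synthParams(leafBlobCount = 2L,
                                         targetLeafArea = 3000,
                                         targetSubstrateArea = 1500,
                                         seed = 4))
  expect_equal(fewBlobs$record$label, "unhealthy")  # blob-count deficit

  expect_error(renderSeedling(synthParams(frameWidth = 50L,
                                          frameHeight = 50L,
                                          targetLeafArea = 2000,
                                          targetSubstrateArea = 10)),
               "infeasible")
})

test_that("rendered pixels land in the HSV ranges the screen measures", {
  set.seed(71)
  r <- renderSeedling(synthParams(leafBlobCount = 3L, targetLeafArea = 2800,
                                  targetSubstrateArea = 1400))
  hsv <- rgbToHsv(r$image)
  tbl <- colorTable()
  leafHits <- sum(unionMasks(hsvInRange(hsv, tbl$green),
                             hsvInRange(hsv, tbl$yellow)) == 255)
  subHits <- sum(hsvInRange(hsv, tbl$black) == 255)
  expect_equal(leafHits, r$record$leafArea)       # every leaf pixel, no more
  expect_equal(subHits, r$record$substrateArea)
})

test_that("generateDataset writes a consistent, reproducible dataset", {
  d1 <- file.path(tempdir(), "synthA")
  d2 <- file.path(tempdir(), "synthB")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- generateDataset(2, seed = 5, outDir = d1, frameWidth = 200L,
                        frameHeight = 160L,
                        thresholds = screeningThresholds(500, 300))
  m2 <- generateDataset(2, seed = 5, outDir = d2, frameWidth = 200L,
                        frameHeight = 160L,
                        thresholds = screeningThresholds(500, 300))
  expect_equal(nrow(m1), 6L)
  expect_equal(as.vector(table(m1$label)), rep(2L, 3))
  expect_equal(m1$label, m2$label)
  expect_equal(m1$split, m2$split)
  # byte-identical renders under the same seed
  h1 <- tools::md5sum(m1$path)
  h2 <- tools::md5sum(m2$path)
  expect_equal(unname(h1), unname(h2))
  expect_true(file.exists(file.path(d1, "manifest.csv")))
  expect_true(file.exists(file.path(d1, "ground_truth.json")))
  gt <- jsonlite::read_json(file.path(d1, "ground_truth.json"))
  expect_length(gt, 6L)
})

test_that("generated labels agree with the rule-based screen", {
  d <- file.path(tempdir(), "synthC")
  unlink(d, recursive = TRUE)
  man <- generateDataset(2, seed = 6, outDir = d)
  recs <- attr(man, "records")
  for (i in seq_len(nrow(man))) {
    img <- readImageRGB(man$path[i])
    res <- screenPhysical(img)
    expect_equal(screenLabel(res), man$label[i])
    if (man$label[i] != "none") {
      a <- screenAreas(res)
      expect_lt(abs(a[["leaf"]] - recs[[i]]$leafArea) /
                  recs[[i]]$leafArea, 0.1)
      expect_lt(abs(a[["substrate"]] - recs[[i]]$substrateArea) /
                  recs[[i]]$substrateArea, 0.1)
    }
  }
})
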