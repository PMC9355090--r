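test_that("rgbToHsv reproduces the hexcone conversion on known pixels", {
  px <- function(rgb) rgbToHsv(array(as.numeric(rgb), dim = c(1, 1, 3)))[1, 1, ]
  expect_equal(px(c(255, 0, 0)), c(0, 255, 255))      # pure red, hue 0
  expect_equal(px(c(0, 255, 0)), c(60, 255, 255))     # 120 deg halved
  expect_equal(px(c(0, 0, 255)), c(120, 255, 255))    # 240 deg halved
  expect_equal(px(c(128, 128, 128)), c(0, 0, 128))    # achromatic gray
  expect_equal(px(c(0, 0, 0)), c(0, 0, 0))            # black: S = V = 0
  expect_equal(px(c(255, 255, 255)), c(0, 0, 255))
  # magenta-ish pixel exercises the negative red-branch hue wrap
  expect_equal(px(c(255, 0, 255))[1], 150)            # 300 deg halved
})

test_that("rgbToHsv matches the reference conversion on corners and random pixels", {
  set.seed(123)
  corners <- t(expand.grid(c(0, 255), c(0, 255), c(0, 255)))
  rnd <- matrix(sample(0:255, 3000, replace = TRUE), nrow = 3)
  rgb <- cbind(corners, rnd)
  n <- ncol(rgb)
  img <- array(as.vector(t(rgb)), dim = c(n, 1, 3))
  mine <- rgbToHsv(img)
  ref <- grDevices::rgb2hsv(rgb[1, ], rgb[2, ], rgb[3, ],
                            maxColorValue = 255)
  expect_lte(max(abs(mine[, 1, 1] - ref["h", ] * 180)), 1)
  expect_lte(max(abs(mine[, 1, 2] - ref["s", ] * 255)), 1)
  expect_lte(max(abs(mine[, 1, 3] - ref["v", ] * 255)), 1)
})

test_that("achromatic pixels have zero saturation and black has zero value", {
  set.seed(7)
  g <- sample(0:255, 50, replace = TRUE)
  img <- array(rep(g, 3), dim = c(50, 1, 3))
  hsv <- rgbToHsv(img)
  expect_true(all(hsv[, , 2] == 0))
  expect_equal(hsv[, 1, 3], as.numeric(g))  # V is the (8-bit) max channel
})

test_that("rgbToHsv rejects malformed input", {
  expect_error(rgbToHsv(matrix(0, 2, 2)), "H x W x 3")
  expect_error(rgbToHsv(array(300, dim = c(1, 1, 3))), "\\[0, 255\\]")
})

test_that("hsvInRange applies inclusive bounds, two-interval hue and negation", {
  tbl <- colorTable()
  hsvPix <- function(h, s, v) array(c(h, s, v), dim = c(1, 1, 3))
  expect_equal(hsvInRange(hsvPix(0, 0, 0), tbl$black)[1, 1], 255)
  expect_equal(hsvInRange(hsvPix(90, 128, 46), tbl$black)[1, 1], 255)
  expect_equal(hsvInRange(hsvPix(60, 255, 255), tbl$green)[1, 1], 255)
  expect_equal(hsvInRange(hsvPix(35, 43, 46), tbl$green)[1, 1], 255)
  expect_equal(hsvInRange(hsvPix(0, 0, 255), tbl$green)[1, 1], 0)  # white
  # red's wrapped hue: both intervals hit, mid hues do not
  expect_equal(hsvInRange(hsvPix(5, 200, 200), tbl$red)[1, 1], 255)
  expect_equal(hsvInRange(hsvPix(170, 200, 200), tbl$red)[1, 1], 255)
  expect_equal(hsvInRange(hsvPix(90, 200, 200), tbl$red)[1, 1], 0)
  # masks are binary and negation complements them exactly
  set.seed(42)
  hsv <- array(c(sample(0:180, 60, TRUE), sample(0:255, 120, TRUE)),
               dim = c(10, 6, 3))
  m <- hsvInRange(hsv, tbl$green)
  mn <- hsvInRange(hsv, tbl$green, negate = TRUE)
  expect_true(all(m %in% c(0, 255)))
  expect_true(all(m + mn == 255))
})

test_that("the shipped color table is complete and self-consistent", {
  tbl <- colorTable()
  expect_setequal(names(tbl),
                  c("black", "gray", "white", "red", "orange", "yellow",
                    "green", "cyan", "blue", "purple"))
  expect_equal(ncol(tbl$red@hue), 2L)
  for (r in tbl) expect_true(validObject(r))
})

test_that("unionMasks is an idempotent commutative associative union", {
  set.seed(99)
  for (i in 1:5) {
    a <- randomMask(8, 7); b <- randomMask(8, 7); c <- randomMask(8, 7)
    zero <- matrix(0, 8, 7)
    expect_equal(unionMasks(a, zero), a)          # identity element
    expect_equal(unionMasks(a, a), a)             # idempotent
    expect_equal(unionMasks(a, b), unionMasks(b, a))
    expect_equal(unionMasks(unionMasks(a, b), c),
                 unionMasks(a, unionMasks(b, c)))
  }
  # disjoint single-pixel masks combine to both pixels set
  p1 <- matrix(0, 3, 3); p1[1, 1] <- 255
  p2 <- matrix(0, 3, 3); p2[3, 3] <- 255
  expect_equal(sum(unionMasks(p1, p2) == 255), 2)
  expect_error(unionMasks(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})
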