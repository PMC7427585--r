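# Scene generator: determinism, ground-truth bookkeeping, gamut and series
# construction.

test_that("rendering is deterministic and truth boxes match the layout", {
  spec <- SceneSpec(seed = 7L)
  b1 <- renderScene(spec)
  b2 <- renderScene(spec)
  expect_identical(sceneImage(b1), sceneImage(b2))
  tb <- truthBoxes(b1)
  expect_equal(sum(tb$label == "POT"), 10)
  expect_equal(sum(tb$label == "QRCODE"), 1)
  expect_length(truthMasks(b1), 10)
  # different noise seed: same geometry, different pixels
  spec2 <- SceneSpec(seed = 7L, noiseSeed = 8L)
  b3 <- renderScene(spec2)
  expect_identical(truthMasks(b3), truthMasks(b1))
  expect_false(identical(sceneImage(b3), sceneImage(b1)))
})

test_that("empty pots drop their truth boxes and masks", {
  b <- renderScene(SceneSpec(seed = 3L, emptyPots = c(2L, 7L)))
  expect_equal(sum(truthBoxes(b)$label == "POT"), 8)
  expect_length(truthMasks(b), 8)
  expect_false("r1c2" %in% names(truthMasks(b)))
})

test_that("truth masks are disjoint, inside their boxes, and in the dual gamut", {
  b <- renderScene(SceneSpec(seed = 21L))
  masks <- truthMasks(b)
  expect_true(all(Reduce(`+`, masks) <= 1L))   # pairwise disjoint
  tb <- truthBoxes(b)
  pots <- tb[tb$label == "POT", ]
  img <- sceneImage(b)
  for (i in seq_along(masks)) {
    idx <- which(masks[[i]] == 1L, arr.ind = TRUE)
    x <- idx[, 2] - 1; y <- idx[, 1] - 1   # 0-based pixel coordinates
    expect_true(all(x >= pots$x0[i] & x < pots$x1[i] &
                    y >= pots$y0[i] & y < pots$y1[i]))
  }
  # every truth pixel passes the HSV rule (and indeed the combined rule)
  tm <- Reduce(`+`, masks)
  expect_identical(hsvMask(img)[tm == 1L], rep(1L, sum(tm)))
  expect_identical(combinedMask(img), tm)
})

test_that("a color cast is recovered by white balancing on QR-white pixels", {
  spec <- SceneSpec(seed = 12L)
  plain <- renderScene(spec)
  gains <- c(0.8, 1.0, 0.9)
  cast <- applyColorCast(sceneImage(plain), gains)
  qr <- truthBoxes(plain)[truthBoxes(plain)$label == "QRCODE", ]
  ref <- estimateWhite(cast, as.numeric(qr[c("x0", "y0", "x1", "y1")]))
  bal <- whiteBalance(cast, ref)
  # QR-white pixels recover within 2 intensity levels per channel
  inBox <- function(a) a[(qr$y0 + 2):(qr$y1 - 1), (qr$x0 + 2):(qr$x1 - 1), ]
  expect_lt(max(abs(inBox(bal) - inBox(sceneImage(plain)))), 2 + 1e-9)
  # plant pixels too (mean absolute difference)
  pm <- Reduce(`+`, truthMasks(plain)) == 1
  for (ch in 1:3)
    expect_lt(mean(abs(bal[, , ch][pm] - sceneImage(plain)[, , ch][pm])), 2)
})

test_that("overlapping layouts are rejected", {
  expect_error(SceneSpec(plateRadius = 10, plantRadius = 9.5), "overflow")
  expect_error(SceneSpec(width = 50), "too small")
})

test_that("series have the scheduled size, linear hue drift and nondecreasing areas", {
  spec <- SceneSpec(seed = 5L, plantRadius = 6.5, plantHues = 55)
  ser <- renderSeries(spec, days = 5, areaGrowthPerDay = 12,
                      hueDriftPerDay = 2, imagesPerDay = 14)
  expect_equal(nrow(ser$manifest), 70)           # 5 days x 14 captures
  expect_equal(length(ser$bundles), 70)
  # filenames parse and are chronologically ordered lexicographically
  expect_identical(ser$manifest$filename, sort(ser$manifest$filename))
  # day-10 hue under 2 deg/day drift from 55 would be 75; check day 4 here
  hues <- unique(ser$truth[ser$truth$day == 4, "truthHue"])
  expect_equal(hues, 55 + 4 * 2)
  # truth areas never decrease over days, for every pot
  for (p in unique(ser$truth$pot)) {
    a <- ser$truth$truthArea[ser$truth$pot == p]
    a <- tapply(a, ser$truth$day[ser$truth$pot == p], unique)
    expect_true(all(diff(a) >= 0))
  }
  # and grow at roughly the requested rate
  a1 <- mean(ser$truth$truthArea[ser$truth$day == 4]) -
        mean(ser$truth$truthArea[ser$truth$day == 0])
  expect_gt(a1, 0.7 * 4 * 12)
  expect_lt(a1, 1.3 * 4 * 12)
})

test_that("series written to disk round-trip through PNG", {
  dir <- withr::local_tempdir()
  spec <- SceneSpec(seed = 9L, plantRadius = 6.5)
  ser <- renderSeries(spec, days = 1, imagesPerDay = 2, dir = dir)
  expect_true(all(file.exists(file.path(dir, ser$manifest$filename))))
  img <- readImageRGB(file.path(dir, ser$manifest$filename[1]))
  direct <- renderScene(SceneSpec(seed = 9L, plantRadius = 6.5,
                                  noiseSeed = (9L * 1009L + 13L) %% 2147483647L))
  expect_identical(img, sceneImage(direct))
})
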