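# Threshold segmentation: canonical pixels, per-pixel oracle equivalence,
# conjunction properties, clutter invariance.

test_that("canonical pixels fall on the right side of each rule", {
  expect_equal(hsvMask(pixelArray(0, 255, 0))[1, 1], 1L)    # pure green, H=120
  expect_equal(hsvMask(pixelArray(0, 0, 255))[1, 1], 0L)    # pure blue, H=240
  expect_equal(hsvMask(pixelArray(255, 255, 255))[1, 1], 0L) # white, S=0
  expect_equal(labMask(pixelArray(0, 255, 0))[1, 1], 1L)    # a* ~ -86, b* ~ +83
  expect_equal(labMask(pixelArray(255, 0, 0))[1, 1], 0L)    # a* ~ +80
  expect_equal(labMask(pixelArray(128, 128, 128))[1, 1], 0L) # neutral axis
})

test_that("masks equal the per-pixel oracles on random pixels", {
  set.seed(42)
  n <- 1500
  px <- matrix(sample(0:255, 3 * n, replace = TRUE), ncol = 3)
  crop <- array(0L, c(n, 1, 3))
  crop[, 1, ] <- px
  hm <- hsvMask(crop)
  lm <- labMask(crop)
  skipped <- 0
  cfg <- ThresholdConfig()
  for (i in seq_len(n)) {
    h <- oracleHsvPixel(px[i, 1], px[i, 2], px[i, 3])
    # pixels landing numerically on a threshold are ambiguous at float
    # precision between two algebraically equivalent conversion routes
    if (min(abs(h[["h"]] - c(cfg@hueMin, cfg@hueMax))) < 1e-6 ||
        min(abs(h[["s"]] - cfg@satMin), abs(h[["v"]] - cfg@valMin)) < 1e-6) {
      skipped <- skipped + 1
    } else {
      expect_identical(hm[i, 1] == 1L, oracleHsvPass(px[i, 1], px[i, 2], px[i, 3]),
                       info = paste("HSV pixel", paste(px[i, ], collapse = ",")))
    }
    expect_identical(lm[i, 1] == 1L, oracleLabPass(px[i, 1], px[i, 2], px[i, 3]),
                     info = paste("Lab pixel", paste(px[i, ], collapse = ",")))
  }
  expect_lt(skipped, n / 100)
})

test_that("the combined mask is the conjunction and a subset of both", {
  b <- renderScene(SceneSpec(seed = 31L))
  img <- sceneImage(b)
  hm <- hsvMask(img); lm <- labMask(img); cm <- combinedMask(img)
  expect_identical(cm, hm * lm)
  expect_true(all(cm <= hm))
  expect_true(all(cm <= lm))
  # a pixel passing only HSV is excluded: orange (30 deg) passes hue but
  # has a* > -4
  orange <- pixelArray(255, 128, 0)
  expect_equal(hsvMask(orange)[1, 1], 1L)
  expect_equal(combinedMask(orange)[1, 1], 0L)
  # full-pass crop gives a full mask
  green <- array(0L, c(4, 4, 3)); green[, , 2] <- 200L
  expect_true(all(combinedMask(green) == 1L))
})

test_that("thresholding ignores excluded-color clutter", {
  b <- renderScene(SceneSpec(seed = 17L))
  img <- sceneImage(b)
  before <- combinedMask(img)
  # paint blue and gray blobs onto background regions
  clutter <- img
  clutter[1:10, 1:10, ] <- rep(c(20L, 30L, 200L), each = 100)    # blue
  clutter[1:10, 21:30, ] <- 120L                                  # gray
  after <- combinedMask(clutter)
  tm <- Reduce(`+`, truthMasks(b))
  expect_identical(after[tm == 1L], before[tm == 1L])
  expect_identical(after, before)   # clutter adds no plant pixels anywhere
})

test_that("synthetic plant crops are recovered exactly", {
  b <- renderScene(SceneSpec(seed = 23L, plantScale = 1.5))
  g <- selectGroup(detectCandidates(sceneImage(b)))
  crops <- cropPots(sceneImage(b), g, 40L)
  for (i in c(1L, 5L, 10L)) {
    expect_identical(combinedMask(crops[[i]]),
                     cropTruthMask(b, g, i, 40L))
  }
})

test_that("masks survive a PNG round trip", {
  m <- matrix(rbinom(400, 1, 0.3), 20)
  path <- withr::local_tempfile(fileext = ".png")
  writeMask(m, path)
  expect_identical(readMask(path), matrix(as.integer(m), 20))
})
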