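# U-net: configuration, analytic gradients vs finite differences, the
# validation split, training smoke behavior and prediction contracts.
# Tests run a reduced network (depth 2-3, 32 px inputs) so the suite stays
# fast; the architecture code paths are identical at any size.

test_that("configuration invariants are enforced", {
  expect_error(UNetConfig(inputSize = 63L), "multiple of 2")
  expect_error(UNetConfig(inputSize = 72L, depth = 4L), "2\\^depth")
  expect_error(UNetConfig(inputSize = 64L, cornerCropSize = 64L), "smaller")
  expect_s4_class(UNetConfig(inputSize = 64L, cornerCropSize = 56L), "UNetConfig")
})

test_that("conv and pooling gradients match finite differences", {
  set.seed(3)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- rnorm(3)
  dy <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  fwd <- function(x, w, b) sum(phenogreen:::.conv2d_fwd(x, w, b) * dy)
  g <- phenogreen:::.conv2d_bwd(x, w, dy)
  eps <- 1e-6
  for (k in sample(length(w), 12)) {
    w2 <- w; w2[k] <- w2[k] + eps
    expect_equal(g$dw[k], (fwd(x, w2, b) - fwd(x, w, b)) / eps, tolerance = 1e-4)
  }
  for (k in sample(length(x), 12)) {
    x2 <- x; x2[k] <- x2[k] + eps
    expect_equal(g$dx[k], (fwd(x2, w, b) - fwd(x, w, b)) / eps, tolerance = 1e-4)
  }
  expect_equal(as.numeric(g$db),
               vapply(1:3, function(c) sum(dy[, , c]), numeric(1)))
  # max pooling: forward picks the max, backward routes gradient to it
  mp <- phenogreen:::.maxpool2_fwd(x)
  expect_equal(mp$y[1, 1, 1], max(x[1:2, 1:2, 1]))
  back <- phenogreen:::.maxpool2_bwd(mp$y * 0 + 1, mp$arg, 6L, 6L)
  expect_equal(sum(back), length(mp$y))
  expect_true(all(back %in% c(0, 1)))
})

test_that("whole-network gradients match finite differences", {
  cfg <- UNetConfig(inputSize = 8L, cornerCropSize = 6L, depth = 2L,
                    baseChannels = 2L, seed = 5L)
  p <- phenogreen:::initUNetWeights(cfg)
  set.seed(9)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  y <- matrix(rbinom(64, 1, 0.3), 8, 8)
  lossAt <- function(p) {
    fw <- phenogreen:::unetForward(p, x, cfg)
    phenogreen:::bceWithLogits(fw$z, y)$loss
  }
  fw <- phenogreen:::unetForward(p, x, cfg, backprop = TRUE)
  lo <- phenogreen:::bceWithLogits(fw$z, y)
  g <- phenogreen:::unetBackward(p, cfg, fw$cache, lo$dz)
  eps <- 1e-6
  for (nm in c("enc1.c1", "bot.c2", "dec1.up", "dec2.c1", "head")) {
    k <- 1L
    p2 <- p
    p2[[nm]]$w[k] <- p2[[nm]]$w[k] + eps
    num <- (lossAt(p2) - lossAt(p)) / eps
    expect_equal(g[[nm]]$w[k], num, tolerance = 1e-3,
                 info = paste("gradient of", nm))
  }
})

test_that("the validation split happens before augmentation", {
  cfg <- UNetConfig(inputSize = 16L, cornerCropSize = 12L, depth = 2L,
                    baseChannels = 2L, epochs = 1L, seed = 2L)
  mk <- function(i) list(image = array((i * 7L) %% 256L, c(16, 16, 3)),
                         mask = matrix(0L, 16, 16))
  pairs <- lapply(1:40, mk)
  split <- withr::with_seed(1, {
    n <- length(pairs)
    round(cfg@validationFraction * n)
  })
  expect_equal(split, 8)   # 40 pairs at 0.2 -> 32 train / 8 validation
  model <- trainUNet(pairs, cfg)
  expect_s4_class(model, "UNetModel")
  expect_false(anyNA(model@lossLog$valLoss))
  expect_error(trainUNet(list(), cfg), "empty")
})

test_that("a short training run learns and prediction is deterministic", {
  cfg <- UNetConfig(inputSize = 32L, cornerCropSize = 28L, depth = 2L,
                    baseChannels = 4L, epochs = 3L, seed = 1L,
                    validationFraction = 0, learningRate = 3e-3)
  # simple color-separable task: green blob on gray background
  mk <- function(seed) {
    set.seed(seed)
    img <- array(120L, c(32, 32, 3))
    msk <- matrix(0L, 32, 32)
    r0 <- sample(4:20, 1); c0 <- sample(4:20, 1)
    msk[r0:(r0 + 8), c0:(c0 + 8)] <- 1L
    img[, , 1][msk == 1L] <- 40L
    img[, , 2][msk == 1L] <- 200L
    img[, , 3][msk == 1L] <- 60L
    list(image = img, mask = msk)
  }
  pairs <- lapply(1:10, mk)
  model <- trainUNet(pairs, cfg)
  expect_lt(tail(model@lossLog$trainLoss, 1), model@lossLog$trainLoss[1])
  held <- mk(99)
  m1 <- predictMask(model, held$image)
  expect_identical(m1, predictMask(model, held$image))
  expect_equal(dim(m1), c(32, 32))
  # an all-background crop yields an almost empty mask
  bg <- array(120L, c(32, 32, 3))
  expect_lt(mean(predictMask(model, bg)), 0.01)
  # smaller crops are padded, larger crops resized; output matches input
  expect_equal(dim(predictMask(model, array(120L, c(16, 16, 3)))), c(16, 16))
  expect_equal(dim(predictMask(model, array(120L, c(64, 64, 3)))), c(64, 64))
  # model round-trips through disk
  path <- withr::local_tempfile(fileext = ".rds")
  saveUNet(model, path)
  expect_identical(predictMask(loadUNet(path), held$image), m1)
})
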