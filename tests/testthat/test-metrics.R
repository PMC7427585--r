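# Segmentation metrics: confusion counts, score identities, brute-force
# oracle agreement, AP at 0.5 IoU.

test_that("confusion counts match hand-counted block layouts", {
  mk <- function(rows, cols, n = 4) {
    m <- matrix(0L, n, n); m[rows, cols] <- 1L; m
  }
  full <- mk(1:2, 1:2)
  expect_equal(confusionCounts(full, full),
               c(tp = 4, fp = 0, tn = 12, fn = 0))
  # disjoint 2x2 blocks in a 4x4 image
  expect_equal(confusionCounts(mk(1:2, 1:2), mk(3:4, 3:4)),
               c(tp = 0, fp = 4, tn = 8, fn = 4))
  # overlapping by exactly one pixel
  expect_equal(confusionCounts(mk(1:2, 1:2), mk(2:3, 2:3)),
               c(tp = 1, fp = 3, tn = 9, fn = 3))
  expect_error(confusionCounts(mk(1, 1), matrix(0L, 3, 3)), "dimensions")
})

test_that("scores match the formulas and the degenerate conventions", {
  s <- segScores(c(tp = 1, fp = 3, tn = 9, fn = 3))
  expect_equal(s[["iou"]], 1 / 7)
  expect_equal(s[["dice"]], 0.25)
  expect_equal(s[["precision"]], 0.25)
  expect_equal(s[["recall"]], 0.25)
  expect_equal(s[["pixelAcc"]], 10 / 16)
  # identical masks score 1 everywhere
  m <- matrix(rbinom(64, 1, 0.4), 8)
  expect_true(all(segScores(m, m) == 1))
  # empty prediction, non-empty truth
  s0 <- segScores(matrix(0L, 4, 4), matrix(c(1L, rep(0L, 15)), 4))
  expect_equal(s0[["recall"]], 0)
  expect_equal(s0[["iou"]], 0)
  # both empty: defined as 1
  sE <- segScores(matrix(0L, 4, 4), matrix(0L, 4, 4))
  expect_true(all(sE[c("iou", "dice", "precision", "recall", "f1")] == 1))
})

test_that("metric identities and the set oracle hold on random mask pairs", {
  set.seed(7)
  for (i in 1:100) {
    pred <- matrix(rbinom(256, 1, runif(1, 0.05, 0.6)), 16)
    truth <- matrix(rbinom(256, 1, runif(1, 0.05, 0.6)), 16)
    s <- segScores(pred, truth)
    o <- oracleSetScores(pred, truth)
    expect_equal(s[["iou"]], o$iou)
    expect_equal(s[["dice"]], o$dice)
    expect_equal(s[["pixelAcc"]], o$pixelAcc)
    # Dice = 2 IoU / (1 + IoU) and F1 == Dice to near machine precision
    expect_equal(s[["dice"]], 2 * s[["iou"]] / (1 + s[["iou"]]),
                 tolerance = 1e-12)
    expect_lt(abs(s[["f1"]] - s[["dice"]]), 1e-12)
    expect_true(s[["iou"]] <= s[["dice"]] && s[["dice"]] <= 1)
  }
})

test_that("average precision reproduces hand-enumerated PR curves", {
  blk <- function(rows, cols) { m <- matrix(0L, 8, 8); m[rows, cols] <- 1L; m }
  t1 <- blk(1:3, 1:3); t2 <- blk(6:8, 6:8)
  # one prediction covering the single truth well
  expect_equal(apAtIoU(list(blk(1:3, 1:3)), 0.9, list(t1)), 1)
  # two predictions, scores 0.9 / 0.8, IoUs 1.0 / ~0.3 against two truths:
  # TP then FP -> precision (1, 0.5), recall (0.5, 0.5) -> AP = 0.5
  lowIoU <- blk(5:8, 5:8)   # IoU with t2 = 9/16 ... shrink overlap instead
  lowIoU <- blk(4:6, 4:6)   # overlaps t2 by 1 pixel -> IoU 1/17
  expect_equal(apAtIoU(list(blk(1:3, 1:3), lowIoU), c(0.9, 0.8),
                       list(t1, t2)), 0.5)
  # all predictions below the threshold
  expect_equal(apAtIoU(list(lowIoU), 0.9, list(t1)), 0)
  expect_error(apAtIoU(list(t1), 0.9, list()), "non-empty")
})

test_that("greedy matching never double-counts a truth instance", {
  blk <- function(rows, cols) { m <- matrix(0L, 8, 8); m[rows, cols] <- 1L; m }
  t1 <- blk(1:4, 1:4)
  # two identical predictions on one truth: second is a false positive
  ap <- apAtIoU(list(t1, t1), c(0.9, 0.8), list(t1))
  expect_equal(ap, 1)   # recall 1 reached at precision 1 before the FP
  counts <- evaluateSegmentation(list(a = t1, b = t1), list(t1, t1))
  expect_equal(nrow(counts$perImage), 2)
})

test_that("evaluateSegmentation writes the per-image CSV", {
  m1 <- matrix(rbinom(64, 1, 0.3), 8); m2 <- matrix(rbinom(64, 1, 0.3), 8)
  path <- withr::local_tempfile(fileext = ".csv")
  res <- evaluateSegmentation(list(x = m1, y = m2), list(m1, m1), file = path)
  got <- read.csv(path)
  expect_equal(got$image_id, c("x", "y"))
  expect_equal(got$iou[1], 1)
})
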