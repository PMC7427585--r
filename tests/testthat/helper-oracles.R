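# Independent per-pixel oracles and small simulation helpers used across
# the test files. The oracles are deliberately scalar (one pixel at a time)
# so they cannot share vectorization shortcuts with the implementation.

# Scalar RGB -> HSV from the textbook hexcone formulas (independent of
# grDevices::rgb2hsv). r, g, b in 0..255; hue in degrees.
oracleHsvPixel <- function(r, g, b) {
  r <- r / 255; g <- g / 255; b <- b / 255
  mx <- max(r, g, b); mn <- min(r, g, b)
  d <- mx - mn
  h <- if (d == 0) 0
  else if (mx == r) 60 * (((g - b) / d) %% 6)
  else if (mx == g) 60 * ((b - r) / d + 2)
  else 60 * ((r - g) / d + 4)
  s <- if (mx == 0) 0 else d / mx
  c(h = h, s = s, v = mx)
}

# Scalar RGB -> CIELAB through grDevices::convertColor called on a single
# pixel (exercises the conversion one pixel at a time, so any vectorization
# shortcut in the mask code would show up as a mismatch).
oracleLabPixel <- function(r, g, b) {
  lab <- grDevices::convertColor(matrix(c(r, g, b) / 255, 1), "sRGB", "Lab")
  c(L = lab[1], a = lab[2], b = lab[3])
}

# Per-pixel threshold decisions from the oracles.
oracleHsvPass <- function(r, g, b, cfg = ThresholdConfig()) {
  h <- oracleHsvPixel(r, g, b)
  h[["h"]] >= cfg@hueMin && h[["h"]] <= cfg@hueMax &&
    h[["s"]] >= cfg@satMin && h[["s"]] <= cfg@satMax &&
    h[["v"]] >= cfg@valMin && h[["v"]] <= cfg@valMax
}

oracleLabPass <- function(r, g, b, cfg = ThresholdConfig()) {
  l <- oracleLabPixel(r, g, b)
  l[["a"]] >= cfg@aMin && l[["a"]] <= cfg@aMax &&
    l[["b"]] >= cfg@bMin && l[["b"]] <= cfg@bMax
}

# Brute-force segmentation scores from explicit pixel index sets.
oracleSetScores <- function(pred, truth) {
  P <- which(pred == 1L); T <- which(truth == 1L)
  N <- length(pred)
  tp <- length(intersect(P, T))
  fp <- length(setdiff(P, T))
  fn <- length(setdiff(T, P))
  tn <- N - tp - fp - fn
  u <- length(union(P, T))
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       iou = if (u == 0) 1 else tp / u,
       dice = if (length(P) + length(T) == 0) 1 else 2 * tp / (length(P) + length(T)),
       pixelAcc = (tp + tn) / N)
}

# A single-pixel RGB array (height 1 x width 1 x 3).
pixelArray <- function(r, g, b) {
  a <- array(0L, c(1, 1, 3))
  a[1, 1, ] <- as.integer(c(r, g, b))
  a
}

# Build 64 x 64 crop/mask training pairs from rendered scenes (two pots per
# scene), optionally under a color cast.
makeCropPairs <- function(seeds, cast = NULL, cropSize = 64L) {
  out <- list()
  for (s in seeds) {
    sp <- SceneSpec(seed = s, plantRadius = 6.5, plantScale = 1.6,
                    plantHues = 60 + (s %% 60),
                    colorCast = if (is.null(cast)) c(1, 1, 1) else cast)
    b <- renderScene(sp)
    g <- selectGroup(detectCandidates(sceneImage(b)))
    crops <- cropPots(sceneImage(b), g, cropSize)
    half <- cropSize %/% 2L
    for (i in c(1L, 6L)) {
      m <- g@members[i, ]
      cx <- floor((m$x0 + m$x1) / 2); cy <- floor((m$y0 + m$y1) / 2)
      tm <- truthMasks(b)[[sprintf("r%dc%d", m$row, m$col)]]
      full <- matrix(0L, cropSize, cropSize)
      xs <- (cx - half):(cx + half - 1L); ys <- (cy - half):(cy + half - 1L)
      okx <- xs >= 0 & xs < ncol(tm); oky <- ys >= 0 & ys < nrow(tm)
      full[which(oky), which(okx)] <- tm[ys[oky] + 1L, xs[okx] + 1L]
      out[[length(out) + 1L]] <- list(image = crops[[i]], mask = full)
    }
  }
  out
}

# Crop a full-scene truth mask to the window cropPots() used for member i.
cropTruthMask <- function(bundle, group, i, cropSize) {
  m <- group@members[i, ]
  half <- cropSize %/% 2L
  cx <- floor((m$x0 + m$x1) / 2); cy <- floor((m$y0 + m$y1) / 2)
  tm <- truthMasks(bundle)[[sprintf("r%dc%d", m$row, m$col)]]
  out <- matrix(0L, cropSize, cropSize)
  xs <- (cx - half):(cx + half - 1L); ys <- (cy - half):(cy + half - 1L)
  okx <- xs >= 0 & xs < ncol(tm); oky <- ys >= 0 & ys < nrow(tm)
  out[which(oky), which(okx)] <- tm[ys[oky] + 1L, xs[okx] + 1L]
  out
}

# Simulate a balanced two-random-effect trait table for heritability
# recovery: y = clover effect + rhizobium effect + noise.
simulateH2Data <- function(nClover, nRhizobium, obsPerClover,
                           varClover, varRhizobium, varResidual, seed) {
  set.seed(seed)
  n <- nClover * obsPerClover
  clover <- rep(sprintf("C%03d", seq_len(nClover)), each = obsPerClover)
  rhizobium <- sprintf("R%03d", sample.int(nRhizobium, n, replace = TRUE))
  effC <- rnorm(nClover, 0, sqrt(varClover))
  effR <- rnorm(nRhizobium, 0, sqrt(varRhizobium))
  data.frame(
    Clover = clover, Rhizobium = rhizobium,
    NS = sample(0:39, n, TRUE), EW = sample(0:44, n, TRUE),
    Round = sample(1:2, n, TRUE), Replicate = sample(1:3, n, TRUE),
    AreaPerDay = effC[as.integer(factor(clover))] +
      effR[as.integer(sub("R", "", rhizobium))] +
      rnorm(n, 0, sqrt(varResidual)),
    stringsAsFactors = FALSE)
}
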