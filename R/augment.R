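# Deterministic 40-fold data augmentation for U-net training:
# {no flip, horizontal flip} x {0, 90, 180, 270 degree rotation} x
# {identity, 4 corner crops rescaled back to full size} = 2 * 4 * 5 = 40
# variants per image/mask pair. The enumeration is exhaustive rather than
# random, so no variant repeats.

flipH <- function(a) {
  if (length(dim(a)) == 3L) a[, dim(a)[2]:1, , drop = FALSE]
  else a[, ncol(a):1, drop = FALSE]
}

# 90-degree clockwise rotation, exact (index permutation)
rot90cw <- function(a) {
  if (length(dim(a)) == 3L) {
    out <- array(a[dim(a)[1]:1, , , drop = FALSE], dim(a))
    aperm(out, c(2, 1, 3))
  } else t(a[nrow(a):1, , drop = FALSE])
}

rotateK <- function(a, k) {
  k <- k %% 4L
  while (k > 0L) { a <- rot90cw(a); k <- k - 1L }
  a
}

cornerCrop <- function(a, corner, size) {
  d <- dim(a)
  rows <- switch(corner, tl = , tr = seq_len(size),
                 bl = , br = (d[1] - size + 1):d[1])
  cols <- switch(corner, tl = , bl = seq_len(size),
                 tr = , br = (d[2] - size + 1):d[2])
  if (length(d) == 3L) a[rows, cols, , drop = FALSE] else a[rows, cols, drop = FALSE]
}

resizeImage <- function(a, size) {
  out <- EBImage::resize(a / 255, w = size, h = size)
  out <- clip255(roundHalfUp(as.array(out) * 255))
  storage.mode(out) <- "integer"
  out
}

resizeMaskNearest <- function(m, size) {
  out <- EBImage::resize(m, w = size, h = size, filter = "none")
  matrix(as.integer(as.array(out) > 0.5), size, size)
}

#' Augment an image/mask training set 40-fold
#'
#' Applies the deterministic augmentation scheme to each pair: flipped and
#' not flipped, rotated by 0, 90, 180 and 270 degrees, and cropped from
#' each of the four corners at `cornerCropSize` (default 460) rescaled back
#' to `inputSize` (default 512; bilinear for images, nearest-neighbor for
#' masks). Variants are enumerated in the fixed order flip, rotation, crop,
#' yielding exactly 40 distinct pairs per input pair.
#'
#' @param pairs list of `list(image =, mask =)` with square
#'   `inputSize x inputSize` images (8-bit RGB arrays) and aligned 0/1
#'   masks.
#' @param cfg a [UNetConfig-class] (uses `inputSize` and
#'   `cornerCropSize`).
#' @return list of `40 * length(pairs)` pairs; names encode the variant
#'   (`<pair>.<flip>.<rot>.<crop>`).
#' @examples
#' \donttest{
#' cfg <- UNetConfig(inputSize = 64L, cornerCropSize = 56L)
#' img <- array(0L, c(64, 64, 3)); msk <- matrix(0L, 64, 64)
#' length(augmentDataset(list(list(image = img, mask = msk)), cfg))   # 40
#' }
#' @export
augmentDataset <- function(pairs, cfg = UNetConfig()) {
  size <- cfg@inputSize
  crop <- cfg@cornerCropSize
  out <- list()
  for (p in seq_along(pairs)) {
    img <- pairs[[p]]$image
    msk <- pairs[[p]]$mask
    d <- dim(img)
    if (d[1] != d[2]) stop("augmentation requires square images")
    if (d[1] != size)
      stop(sprintf("images must be inputSize x inputSize (%d), got %d", size, d[1]))
    if (!identical(dim(msk), d[1:2])) stop("mask dimensions must match image")
    for (flip in c("n", "f")) {
      fi <- if (flip == "f") flipH(img) else img
      fm <- if (flip == "f") flipH(msk) else msk
      for (rot in c(0L, 90L, 180L, 270L)) {
        ri <- rotateK(fi, rot %/% 90L)
        rm <- rotateK(fm, rot %/% 90L)
        for (cc in c("id", "tl", "tr", "bl", "br")) {
          if (cc == "id") { ci <- ri; cm <- rm }
          else {
            ci <- resizeImage(cornerCrop(ri, cc, crop), size)
            cm <- resizeMaskNearest(cornerCrop(rm, cc, crop), size)
          }
          out[[sprintf("%03d.%s.%03d.%s", p, flip, rot, cc)]] <-
            list(image = ci, mask = cm)
        }
      }
    }
  }
  out
}
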