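# White balance against the QR fiducial. The white background of the QR
# code serves as the white reference; the black modules are excluded by a
# value-percentile rule, and each channel is stretched multiplicatively so
# the reference becomes neutral white.

#' Estimate the white reference inside a QR detection
#'
#' White pixels are those inside the QR box whose value channel (max of
#' R, G, B) reaches the 75th percentile of the box, which excludes the
#' black QR modules; the reference is the per-channel mean over that set.
#' A box without contrast (nothing below the threshold, e.g. fully black
#' or fully white) gives no usable reference and errors.
#'
#' @param image 8-bit RGB array.
#' @param qrBox QRCODE detection: numeric (x0, y0, x1, y1) or a single box
#'   row with `label == "QRCODE"`.
#' @return a [WhiteReference-class].
#' @section Errors: `pgWhiteUnreliable` when fewer than 50 white pixels are
#'   found (e.g. an all-black or degenerate box).
#' @export
estimateWhite <- function(image, qrBox) {
  d <- stopIfNot8bitRGB(image)
  if (is.data.frame(qrBox)) {
    if (!identical(qrBox$label, "QRCODE")) stop("qrBox must have label QRCODE")
    qrBox <- as.numeric(qrBox[1, c("x0", "y0", "x1", "y1")])
  }
  xs <- max(1L, floor(qrBox[1]) + 1L):min(d[2], ceiling(qrBox[3]))
  ys <- max(1L, floor(qrBox[2]) + 1L):min(d[1], ceiling(qrBox[4]))
  sub <- image[ys, xs, , drop = FALSE]
  v <- pmax(sub[, , 1], sub[, , 2], sub[, , 3])
  thr <- quantile(v, 0.75)
  white <- v >= thr
  if (all(white))  # no pixels below the threshold: box has no dark modules
    pgError("pgWhiteUnreliable",
            "white reference unreliable: QR box has no contrast")
  if (sum(white) < 50)
    pgError("pgWhiteUnreliable",
            sprintf("white reference unreliable: %d white pixels (< 50)", sum(white)))
  means <- vapply(1:3, function(ch) mean(sub[, , ch][white]), numeric(1))
  new("WhiteReference", region = as.numeric(qrBox),
      channelMeans = means, nWhite = as.integer(sum(white)))
}

#' White-balance an image against a white reference
#'
#' Stretches each color channel by `255 / channelMean`, clipping to
#' \[0, 255\] and rounding half up. Re-estimating the reference on the
#' output gives unit gains up to rounding (idempotence).
#'
#' @param image 8-bit RGB array.
#' @param ref a [WhiteReference-class] from [estimateWhite()].
#' @return balanced image, integer 0..255, same shape.
#' @examples
#' img <- array(c(100L, 200L, 150L), c(1, 1, 3))
#' ref <- new("WhiteReference", region = c(0, 0, 1, 1),
#'            channelMeans = c(200, 250, 220), nWhite = 50L)
#' whiteBalance(img, ref)[1, 1, ]   # 128, 204, 174
#' @export
whiteBalance <- function(image, ref) {
  stopIfNot8bitRGB(image)
  out <- image
  # multiply before dividing so exact halves (e.g. 100 * 255 / 200) round up
  for (ch in 1:3)
    out[, , ch] <- clip255(roundHalfUp(image[, , ch] * 255 / ref@channelMeans[ch]))
  storage.mode(out) <- "integer"
  out
}

#' @describeIn WhiteReference-class compact display
#' @param object a WhiteReference
#' @export
setMethod("show", "WhiteReference", function(object) {
  cat(sprintf("WhiteReference: means (%.1f, %.1f, %.1f) from %d white pixels\n",
              object@channelMeans[1], object@channelMeans[2],
              object@channelMeans[3], object@nWhite))
})
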