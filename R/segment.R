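# Dual-colorspace threshold segmentation. A pixel counts as plant when the
# HSV rule (hue 30-150 degrees, S and V in 0.2-1) and the CIELAB rule
# (a* <= -4, b* >= 4; D65, 2 degree observer) agree, i.e. the pixelwise AND
# of the two masks. Conversions are delegated to grDevices (rgb2hsv,
# convertColor).

#' Default dual-colorspace thresholds
#'
#' Constructor for [ThresholdConfig-class] with the standard bounds: hue
#' 30-150 degrees, saturation and value 0.2-1, a* in \[-128, -4\], b* in
#' \[4, 128\]. All bounds are inclusive.
#'
#' @param hueMin,hueMax,satMin,satMax,valMin,valMax HSV bounds.
#' @param aMin,aMax,bMin,bMax CIELAB bounds.
#' @return a validated [ThresholdConfig-class].
#' @export
ThresholdConfig <- function(hueMin = 30, hueMax = 150,
                            satMin = 0.2, satMax = 1,
                            valMin = 0.2, valMax = 1,
                            aMin = -128, aMax = -4, bMin = 4, bMax = 128) {
  new("ThresholdConfig", hueMin = hueMin, hueMax = hueMax,
      satMin = satMin, satMax = satMax, valMin = valMin, valMax = valMax,
      aMin = aMin, aMax = aMax, bMin = bMin, bMax = bMax)
}

# Flatten an RGB array (H x W x 3) to an n x 3 matrix of 0..255 values.
flattenRGB <- function(image) {
  d <- stopIfNot8bitRGB(image)
  matrix(as.numeric(image), d[1] * d[2], 3L)
}

# HSV of an n x 3 RGB (0..255) matrix; hue in degrees, s/v in [0, 1].
rgbToHsvMat <- function(px) {
  h <- grDevices::rgb2hsv(t(px), maxColorValue = 255)
  cbind(h = h[1, ] * 360, s = h[2, ], v = h[3, ])
}

# CIELAB (D65, 2 degree observer) of an n x 3 RGB (0..255) matrix.
rgbToLabMat <- function(px) {
  lab <- grDevices::convertColor(px / 255, from = "sRGB", to = "Lab")
  colnames(lab) <- c("L", "a", "b")
  lab
}

passesHsvRule <- function(px, cfg) {
  hsv <- rgbToHsvMat(px)
  hsv[, "h"] >= cfg@hueMin & hsv[, "h"] <= cfg@hueMax &
    hsv[, "s"] >= cfg@satMin & hsv[, "s"] <= cfg@satMax &
    hsv[, "v"] >= cfg@valMin & hsv[, "v"] <= cfg@valMax
}

passesLabRule <- function(px, cfg) {
  lab <- rgbToLabMat(px)
  lab[, "a"] >= cfg@aMin & lab[, "a"] <= cfg@aMax &
    lab[, "b"] >= cfg@bMin & lab[, "b"] <= cfg@bMax
}

passesCombinedRule <- function(px, cfg) passesHsvRule(px, cfg) & passesLabRule(px, cfg)

#' Threshold segmentation masks
#'
#' `hsvMask()` keeps pixels whose hue lies in \[30, 150\] degrees with
#' saturation and value in \[0.2, 1\] (capturing yellow and green without
#' orange or blue, excluding pale gray and dark pixels); `labMask()` keeps
#' pixels with a CIELAB green component (a* <= -4) and a yellow component
#' (b* >= 4); `combinedMask()` is their pixelwise AND, the mask used for
#' plant area measurements.
#'
#' @param crop 8-bit RGB array (height x width x 3, values 0..255).
#' @param cfg a [ThresholdConfig-class] (defaults to the standard bounds).
#' @return integer 0/1 matrix with the crop's dimensions.
#' @examples
#' px <- array(0L, c(1, 1, 3)); px[1, 1, 2] <- 255L   # pure green
#' hsvMask(px); labMask(px); combinedMask(px)
#' @export
hsvMask <- function(crop, cfg = ThresholdConfig()) {
  d <- stopIfNot8bitRGB(crop)
  matrix(as.integer(passesHsvRule(flattenRGB(crop), cfg)), d[1], d[2])
}

#' @rdname hsvMask
#' @export
labMask <- function(crop, cfg = ThresholdConfig()) {
  d <- stopIfNot8bitRGB(crop)
  matrix(as.integer(passesLabRule(flattenRGB(crop), cfg)), d[1], d[2])
}

#' @rdname hsvMask
#' @export
combinedMask <- function(crop, cfg = ThresholdConfig()) {
  hsvMask(crop, cfg) * labMask(crop, cfg)
}

#' Write a binary mask as PNG
#'
#' Masks are written as 8-bit grayscale PNG with values 0 and 255.
#'
#' @param mask 0/1 matrix.
#' @param path output file.
#' @export
writeMask <- function(mask, path) png::writePNG(mask * 1.0, path)

#' Read a 0/255 PNG mask back as a 0/1 matrix
#'
#' @param path PNG file written by [writeMask()].
#' @return integer 0/1 matrix.
#' @export
readMask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}
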