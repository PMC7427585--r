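#' @import methods
#' @importFrom stats median quantile sd var lm coef runif rnorm setNames
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib phenogreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Scene specification for the synthetic greenhouse generator
#'
#' Describes one synthetic top-view greenhouse scene: a 2 x 5 block of dark
#' circular plates on a light table, green/yellow plant blobs with known
#' ground-truth masks, a central white QR fiducial, optional decoy pots
#' outside the target group, and an optional global multiplicative color
#' cast. All randomness derives from `seed` (layout, plate shades, QR module
#' pattern) and `noiseSeed` (per-pixel color sampling), so identical specs
#' render bit-identical scenes.
#'
#' @slot width,height image dimensions in pixels (NA = auto-sized from the
#'   layout).
#' @slot rows,cols pot grid layout (default 2 x 5).
#' @slot plateRadius radius of the dark plate under each pot, pixels.
#' @slot plantRadius base radius of the plant blob, pixels; actual extent is
#'   up to ~1.1 x this value (leaflets).
#' @slot plantScale per-pot multiplicative scale on `plantRadius` (length 1
#'   or `rows * cols`); used by [renderSeries()] to grow plants.
#' @slot plantHues nominal hue (degrees) per pot, length 1 or `rows * cols`.
#'   Pixels are drawn with hues inside `plantHue +- 10` degrees, restricted
#'   to the sub-band that passes both segmentation threshold rules.
#' @slot emptyPots integer positions (row-major, 1..rows*cols) rendered with
#'   neither plate nor plant.
#' @slot qrCenter pixel (x, y) of the QR fiducial center (NA = centroid of
#'   the pot block).
#' @slot qrSize side length of the white QR square, pixels (NA = auto).
#' @slot colorCast per-channel multiplicative gains applied to the final
#'   image (default c(1, 1, 1) = no cast). Gains must be positive.
#' @slot extraPots number of decoy pots placed in the same rows but outside
#'   the target group (0..8).
#' @slot seed,noiseSeed integer seeds; `noiseSeed` defaults to `seed` and is
#'   varied by [renderSeries()] so scene geometry stays fixed while pixel
#'   noise differs between captures.
#' @seealso [SceneSpec()], [renderScene()], [renderSeries()]
#' @export
setClass("SceneSpec", representation(
  width = "numeric", height = "numeric",
  rows = "integer", cols = "integer",
  plateRadius = "numeric", plantRadius = "numeric",
  plantScale = "numeric", plantHues = "numeric",
  emptyPots = "integer",
  qrCenter = "numeric", qrSize = "numeric",
  colorCast = "numeric", extraPots = "integer",
  seed = "integer", noiseSeed = "integer"
))

setValidity("SceneSpec", function(object) {
  msg <- character()
  n <- object@rows * object@cols
  if (object@rows < 1L || object@cols < 2L)
    msg <- c(msg, "layout must have at least 1 row and 2 columns")
  if (!length(object@plantHues) %in% c(1L, n))
    msg <- c(msg, "plantHues must have length 1 or rows*cols")
  if (!length(object@plantScale) %in% c(1L, n))
    msg <- c(msg, "plantScale must have length 1 or rows*cols")
  if (any(object@plantHues < 0) || any(object@plantHues >= 360))
    msg <- c(msg, "plantHues must lie in [0, 360)")
  if (length(object@colorCast) != 3L || any(object@colorCast <= 0))
    msg <- c(msg, "colorCast must be 3 positive gains")
  if (any(object@emptyPots < 1L) || any(object@emptyPots > n))
    msg <- c(msg, "emptyPots out of range")
  if (object@extraPots < 0L || object@extraPots > 8L)
    msg <- c(msg, "extraPots must be in 0..8")
  if (object@plantRadius * max(object@plantScale) * 1.15 > object@plateRadius)
    msg <- c(msg, "plants would overflow their plates (layout overlap)")
  geo <- sceneGeometry(object)
  if (!is.na(object@width) && object@width < geo$minWidth)
    msg <- c(msg, sprintf("width %d too small for layout (need >= %d)",
                          as.integer(object@width), geo$minWidth))
  if (!is.na(object@height) && object@height < geo$minHeight)
    msg <- c(msg, sprintf("height %d too small for layout (need >= %d)",
                          as.integer(object@height), geo$minHeight))
  if (geo$qrSize > geo$dy - 2 * object@plateRadius - 2)
    msg <- c(msg, "QR square overlaps the plates (layout overlap)")
  qc <- geo$qrCenter
  if (qc[1] < min(geo$potX) || qc[1] > max(geo$potX) ||
      qc[2] < min(geo$potY) || qc[2] > max(geo$potY))
    msg <- c(msg, "qrCenter must lie inside the hull of the pot block")
  if (length(msg)) msg else TRUE
})

#' Rendered synthetic scene with exact ground truth
#'
#' The output of [renderScene()]: an 8-bit RGB image together with the exact
#' per-pot ground-truth masks, labeled truth boxes (one POT box per
#' non-empty pot, one QRCODE box, decoy boxes kept separately), per-pot
#' barcodes, and the generating [SceneSpec-class].
#'
#' @slot image integer array `height x width x 3`, values 0..255.
#' @slot truthMasks named list of full-scene 0/1 integer matrices, one per
#'   non-empty pot, named `"r<row>c<col>"`.
#' @slot truthBoxes data.frame of detection boxes (label, x0, y0, x1, y1,
#'   score) in 0-based half-open pixel coordinates: POT boxes in row-major
#'   pot order then the QRCODE box.
#' @slot decoyBoxes data.frame of the decoy pots' boxes (not part of the
#'   target group's truth).
#' @slot barcodes character vector of per-pot barcodes, row-major.
#' @slot spec the generating [SceneSpec-class].
#' @export
setClass("SceneBundle", representation(
  image = "array", truthMasks = "list",
  truthBoxes = "data.frame", decoyBoxes = "data.frame",
  barcodes = "character", spec = "SceneSpec"
))

setValidity("SceneBundle", function(object) {
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L) return("image must be height x width x 3")
  ok <- vapply(object@truthMasks, function(m)
    identical(dim(m), d[1:2]) && all(m %in% c(0L, 1L)), logical(1))
  if (!all(ok)) return("truth masks must be full-scene 0/1 matrices")
  TRUE
})

#' Dual-colorspace segmentation thresholds
#'
#' Threshold configuration for plant/background segmentation. A pixel is
#' plant when it passes the HSV rule (hue in \[30, 150\] degrees, saturation
#' and value in \[0.2, 1\]) *and* the CIELAB rule (a* <= -4 and b* >= 4,
#' i.e. a green and a yellow component), keeping green and yellow pixels and
#' their mixture while excluding orange, blue, gray and dark pixels.
#'
#' @slot hueMin,hueMax hue bounds in degrees (defaults 30, 150).
#' @slot satMin,satMax saturation bounds in \[0, 1\] (defaults 0.2, 1).
#' @slot valMin,valMax value bounds in \[0, 1\] (defaults 0.2, 1).
#' @slot aMin,aMax CIELAB a* bounds (defaults -128, -4).
#' @slot bMin,bMax CIELAB b* bounds (defaults 4, 128).
#' @seealso [ThresholdConfig()], [hsvMask()], [labMask()], [combinedMask()]
#' @export
setClass("ThresholdConfig", representation(
  hueMin = "numeric", hueMax = "numeric",
  satMin = "numeric", satMax = "numeric",
  valMin = "numeric", valMax = "numeric",
  aMin = "numeric", aMax = "numeric",
  bMin = "numeric", bMax = "numeric"
))

setValidity("ThresholdConfig", function(object) {
  msg <- character()
  if (object@hueMin < 0 || object@hueMax >= 360 || object@hueMin > object@hueMax)
    msg <- c(msg, "hue bounds must satisfy 0 <= hueMin <= hueMax < 360")
  for (p in list(c("satMin", "satMax"), c("valMin", "valMax"),
                 c("aMin", "aMax"), c("bMin", "bMax")))
    if (slot(object, p[1]) > slot(object, p[2]))
      msg <- c(msg, sprintf("%s > %s", p[1], p[2]))
  if (object@aMin < -128 || object@aMax > 128 ||
      object@bMin < -128 || object@bMax > 128)
    msg <- c(msg, "a*/b* bounds must lie in [-128, 128]")
  if (length(msg)) msg else TRUE
})

#' U-net training configuration
#'
#' @slot inputSize network input resolution in pixels; must be divisible by
#'   `2^depth` so each pooling level halves cleanly (default 512).
#' @slot cornerCropSize side of the four corner crops used by the
#'   augmentation scheme, rescaled back to `inputSize` (default 460).
#' @slot epochs training epochs (default 30).
#' @slot validationFraction fraction of pairs held out for validation before
#'   any augmentation (default 0.2).
#' @slot depth number of down/up-sampling levels (default 4).
#' @slot baseChannels channels of the first encoder level (default 16);
#'   doubled at each level.
#' @slot learningRate Adam learning rate (default 1e-3).
#' @slot seed integer seed for weight initialization and shuffling.
#' @seealso [UNetConfig()], [trainUNet()], [augmentDataset()]
#' @export
setClass("UNetConfig", representation(
  inputSize = "integer", cornerCropSize = "integer",
  epochs = "integer", validationFraction = "numeric",
  depth = "integer", baseChannels = "integer",
  learningRate = "numeric", seed = "integer"
))

setValidity("UNetConfig", function(object) {
  msg <- character()
  if (object@inputSize %% 2L != 0L)
    msg <- c(msg, "inputSize must be a multiple of 2")
  if (object@inputSize %% 2L^object@depth != 0L)
    msg <- c(msg, "inputSize must be divisible by 2^depth")
  if (object@cornerCropSize >= object@inputSize)
    msg <- c(msg, "cornerCropSize must be smaller than inputSize")
  if (object@validationFraction < 0 || object@validationFraction >= 1)
    msg <- c(msg, "validationFraction must be in [0, 1)")
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Trained U-net model
#'
#' Holds the weights of a small encoder/decoder segmentation network with
#' skip connections and a sigmoid output, plus its configuration and the
#' per-epoch loss log from training.
#'
#' @slot weights list of parameter tensors (conv kernels and biases).
#' @slot config the [UNetConfig-class] used for training.
#' @slot lossLog data.frame with one row per epoch: epoch, trainLoss,
#'   valLoss (NA when no validation split).
#' @seealso [trainUNet()], [predictMask()], [saveUNet()]
#' @export
setClass("UNetModel", representation(
  weights = "list", config = "UNetConfig", lossLog = "data.frame"
))

#' White reference estimated from the QR fiducial
#'
#' @slot region the QR detection box the reference was estimated in
#'   (numeric x0, y0, x1, y1).
#' @slot channelMeans mean R, G, B intensity of the white pixels (those whose
#'   value channel exceeds the 75th percentile of the box, excluding the
#'   black QR modules), each in (0, 255].
#' @slot nWhite number of white pixels used.
#' @seealso [estimateWhite()], [whiteBalance()]
#' @export
setClass("WhiteReference", representation(
  region = "numeric", channelMeans = "numeric", nWhite = "integer"
))

setValidity("WhiteReference", function(object) {
  if (length(object@channelMeans) != 3L ||
      any(object@channelMeans <= 0) || any(object@channelMeans > 255))
    return("channelMeans must be 3 values in (0, 255]")
  TRUE
})

#' A selected group of ten pots and its QR fiducial
#'
#' The result of [selectGroup()]: the `rows x cols` (default 2 x 5) grid of
#' pot boxes anchored by the QR code, in row-major order. Grid positions with
#' no detected pot (empty pots) are kept as rows with `present = FALSE`.
#'
#' @slot members data.frame with one row per grid position: row, col
#'   (1-based), x0, y0, x1, y1, score, present, and (after
#'   [assignBarcodes()]) ns, ew, barcode.
#' @slot qr numeric QR box (x0, y0, x1, y1).
#' @slot rows,cols grid dimensions.
#' @export
setClass("PlantGroup", representation(
  members = "data.frame", qr = "numeric",
  rows = "integer", cols = "integer"
))

setValidity("PlantGroup", function(object) {
  if (nrow(object@members) != object@rows * object@cols)
    return("members must have one row per grid position")
  if (length(object@qr) != 4L) return("qr must be (x0, y0, x1, y1)")
  TRUE
})

#' Camera uptime and throughput report
#'
#' Image-accounting summary for a capture schedule: expected image counts
#' (days of operation x images per day x cameras), received counts, and
#' per-camera uptime percentages, with average/worst/best camera statistics.
#' Percentages are carried exact and rounded half-up only for display.
#'
#' @slot operationDays,imagesPerDay,nCameras the schedule.
#' @slot expectedPerCamera,expectedTotal expected image counts.
#' @slot receivedTotal images actually received.
#' @slot uptimePct exact overall uptime percentage.
#' @slot perCamera data.frame: cameraId, received, uptimePct.
#' @slot unparseable filenames that did not parse (counted separately,
#'   never silently dropped).
#' @seealso [summarizeInventory()], [expectedImages()], [uptimePct()]
#' @export
setClass("UptimeReport", representation(
  operationDays = "integer", imagesPerDay = "integer", nCameras = "integer",
  expectedPerCamera = "numeric", expectedTotal = "numeric",
  receivedTotal = "numeric", uptimePct = "numeric",
  perCamera = "data.frame", unparseable = "character"
))

#' Broad-sense heritability from variance components
#'
#' Partition of phenotypic variance into host-genotype (clover), symbiont
#' (rhizobium) and residual components; each heritability is the component
#' divided by the sum of the three.
#'
#' @slot varClover,varRhizobium,varResidual variance components.
#' @slot h2Clover,h2Rhizobium,h2Sum heritability fractions in \[0, 1\];
#'   `h2Sum = h2Clover + h2Rhizobium`.
#' @seealso [h2FromVarComps()], [fitHeritability()]
#' @export
setClass("HeritabilityResult", representation(
  varClover = "numeric", varRhizobium = "numeric", varResidual = "numeric",
  h2Clover = "numeric", h2Rhizobium = "numeric", h2Sum = "numeric"
))

setValidity("HeritabilityResult", function(object) {
  h <- c(object@h2Clover, object@h2Rhizobium, object@h2Sum)
  if (any(h < 0) || any(h > 1)) return("heritabilities must lie in [0, 1]")
  if (abs(object@h2Sum - object@h2Clover - object@h2Rhizobium) > 1e-8)
    return("h2Sum must equal h2Clover + h2Rhizobium")
  TRUE
})
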