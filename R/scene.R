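# Synthetic greenhouse scene generator: dark circular plates on a light
# table, plant blobs built from overlapping "leaflet" ellipses, a central
# white QR fiducial, optional decoy pots and a global color cast. Stands in
# for greenhouse camera images so every downstream stage can be tested
# against exact ground truth.

#' Create a scene specification
#'
#' Constructor for [SceneSpec-class]. With all defaults this describes one
#' 2 x 5 block of ten potted plants with a central QR fiducial, auto-sized
#' to the pot layout.
#'
#' @param rows,cols pot grid (default 2 x 5).
#' @param plateRadius,plantRadius plate and base plant radii in pixels.
#' @param plantHues nominal hue in degrees per pot (length 1 or rows*cols).
#' @param plantScale per-pot scale factor on `plantRadius`.
#' @param emptyPots integer grid positions (row-major) left without plate or
#'   plant.
#' @param extraPots number of decoy pots (0..8) placed in the same rows but
#'   outside the target group.
#' @param colorCast per-channel multiplicative gains (default no cast).
#' @param width,height,qrCenter,qrSize optional geometry overrides (NA =
#'   derived from the layout).
#' @param seed integer seed for scene geometry (leaflet shapes, plate
#'   shades, QR pattern).
#' @param noiseSeed integer seed for per-pixel color sampling (defaults to
#'   `seed`); [renderSeries()] varies it between captures.
#' @return a validated [SceneSpec-class] object.
#' @examples
#' spec <- SceneSpec(plateRadius = 16, plantRadius = 6, seed = 1)
#' bundle <- renderScene(spec)
#' dim(sceneImage(bundle))
#' @export
SceneSpec <- function(rows = 2L, cols = 5L, plateRadius = 16, plantRadius = 6,
                      plantHues = 100, plantScale = 1, emptyPots = integer(),
                      extraPots = 0L, colorCast = c(1, 1, 1),
                      width = NA_real_, height = NA_real_,
                      qrCenter = c(NA_real_, NA_real_), qrSize = NA_real_,
                      seed = 1L, noiseSeed = NA_integer_) {
  if (is.na(noiseSeed)) noiseSeed <- as.integer(seed)
  new("SceneSpec",
      width = as.numeric(width), height = as.numeric(height),
      rows = as.integer(rows), cols = as.integer(cols),
      plateRadius = as.numeric(plateRadius),
      plantRadius = as.numeric(plantRadius),
      plantScale = as.numeric(plantScale),
      plantHues = as.numeric(plantHues),
      emptyPots = as.integer(emptyPots),
      qrCenter = as.numeric(qrCenter), qrSize = as.numeric(qrSize),
      colorCast = as.numeric(colorCast), extraPots = as.integer(extraPots),
      seed = as.integer(seed), noiseSeed = as.integer(noiseSeed))
}

# Deterministic layout geometry derived from a SceneSpec. Pot spacing is
# proportional to the plate radius; decoy pots extend the rows sideways.
sceneGeometry <- function(spec) {
  r <- spec@plateRadius
  dx <- 2.4 * r
  dy <- 3.2 * r
  sideCols <- if (spec@extraPots > 4L) 2L else if (spec@extraPots > 0L) 1L else 0L
  minWidth <- ceiling(dx * (spec@cols - 1 + 2 * sideCols) + 2 * (r + 4))
  minHeight <- ceiling(dy * (spec@rows - 1) + 2 * (r + 4))
  width <- if (is.na(spec@width)) minWidth else as.integer(spec@width)
  height <- if (is.na(spec@height)) minHeight else as.integer(spec@height)
  potX <- width / 2 + (seq_len(spec@cols) - (spec@cols + 1) / 2) * dx
  potY <- height / 2 + (seq_len(spec@rows) - (spec@rows + 1) / 2) * dy
  qrCenter <- spec@qrCenter
  if (anyNA(qrCenter)) qrCenter <- c(mean(potX), mean(potY))
  qrSize <- spec@qrSize
  if (is.na(qrSize)) qrSize <- max(10, min(40, floor(dy - 2 * r - 4)))
  # decoy pots: alternate right/left just beyond the target columns
  decoySlots <- list(c(1, spec@cols + 1L), c(spec@rows, 0L),
                     c(spec@rows, spec@cols + 1L), c(1, 0L),
                     c(1, spec@cols + 2L), c(spec@rows, -1L),
                     c(spec@rows, spec@cols + 2L), c(1, -1L))
  decoys <- decoySlots[seq_len(spec@extraPots)]
  decoyXY <- lapply(decoys, function(rc) {
    c(x = width / 2 + (rc[2] - (spec@cols + 1) / 2) * dx, y = potY[rc[1]])
  })
  list(width = as.integer(width), height = as.integer(height),
       minWidth = as.integer(minWidth), minHeight = as.integer(minHeight),
       dx = dx, dy = dy, potX = potX, potY = potY,
       qrCenter = qrCenter, qrSize = qrSize, decoyXY = decoyXY)
}

# Sample the time-invariant geometry parameters (one RNG stream from
# spec@seed): background shade, QR module pattern, per-pot leaflet layouts
# and plate shades. Leaflets all contain the pot center (offset < radial
# semi-axis), so scaling a plant about its center is set-monotone and truth
# areas never decrease as the plant grows.
sampleSceneParams <- function(spec) {
  nPot <- spec@rows * spec@cols
  withSeed(spec@seed, {
    bgGray <- round(runif(1, 192, 206))
    qrPattern <- matrix(runif(49) < 0.5, 7, 7)
    qrPattern[1:3, 1:3] <- TRUE
    qrPattern[1:3, 5:7] <- TRUE
    qrPattern[5:7, 1:3] <- TRUE
    qrPattern[2, 2] <- qrPattern[2, 6] <- qrPattern[6, 2] <- FALSE
    potPar <- lapply(seq_len(nPot + length(sceneGeometry(spec)$decoyXY)),
      function(i) {
        nLeaf <- 5L
        list(theta = 2 * pi * seq_len(nLeaf) / nLeaf + runif(nLeaf, -0.25, 0.25),
             rho = runif(nLeaf, 0.30, 0.50),
             aRad = runif(nLeaf, 0.55, 0.65),
             bTan = runif(nLeaf, 0.28, 0.38),
             plateShade = round(runif(1, 22, 40)))
      })
    list(bgGray = bgGray, qrPattern = qrPattern, potPar = potPar)
  })
}

# Rasterize one plant (union of leaflet ellipses) as a full-scene 0/1 mask.
rasterizePlant <- function(par, cx, cy, r, width, height) {
  ext <- ceiling(max(par$rho + par$aRad) * r) + 1L
  xs <- max(1L, floor(cx - ext)):min(width, ceiling(cx + ext))
  ys <- max(1L, floor(cy - ext)):min(height, ceiling(cy + ext))
  u <- outer(rep(1, length(ys)), xs - cx)       # x offsets
  v <- outer(ys - cy, rep(1, length(xs)))       # y offsets
  inside <- matrix(FALSE, length(ys), length(xs))
  for (k in seq_along(par$theta)) {
    s <- u * cos(par$theta[k]) + v * sin(par$theta[k]) - par$rho[k] * r
    t <- -u * sin(par$theta[k]) + v * cos(par$theta[k])
    inside <- inside | (s / (par$aRad[k] * r))^2 + (t / (par$bTan[k] * r))^2 <= 1
  }
  mask <- matrix(0L, height, width)
  mask[ys, xs] <- mask[ys, xs] + inside
  mask
}

# Sample plant pixel colors inside the dual-threshold gamut. Hues are drawn
# uniformly in [hue - 10, hue + 10] clipped to [55, 150] (the sub-band whose
# 8-bit quantization passes both the HSV and the CIELAB rule at any
# S in [0.4, 1], V in [0.4, 0.9]); quantized pixels that still fail (rare
# boundary effects) are resampled, with a deterministic mid-green fallback.
samplePlantColors <- function(n, hue, cfg) {
  lo <- max(hue - 10, 55)
  hi <- min(hue + 10, 150)
  if (lo > hi) { lo <- 118; hi <- 122 }
  draw <- function(m) {
    rgb01 <- hsv2rgbMat(runif(m, lo, hi), runif(m, 0.4, 1), runif(m, 0.4, 0.9))
    roundHalfUp(rgb01 * 255)
  }
  px <- draw(n)
  for (i in 1:8) {
    bad <- !passesCombinedRule(px, cfg)
    if (!any(bad)) break
    px[bad, ] <- draw(sum(bad))
  }
  bad <- !passesCombinedRule(px, cfg)
  if (any(bad))
    px[bad, ] <- matrix(roundHalfUp(hsv2rgbMat(120, 0.7, 0.7) * 255),
                        sum(bad), 3, byrow = TRUE)
  px
}

#' Render a synthetic greenhouse scene
#'
#' Deterministically renders the scene described by a [SceneSpec-class]:
#' identical spec (including seeds) gives a bit-identical image. Plant
#' pixels are drawn inside the acceptance gamut of the default segmentation
#' thresholds (so the combined HSV/CIELAB mask recovers the truth masks
#' exactly on uncast scenes), plates are dark gray (value < 0.2), the table
#' is light gray, and the QR fiducial is a white square with black interior
#' modules. The color cast, if any, is applied to the assembled image.
#'
#' @param spec a [SceneSpec-class].
#' @return a [SceneBundle-class] with the image, per-pot truth masks, truth
#'   boxes (POT per non-empty pot, one QRCODE), decoy boxes and barcodes.
#' @export
renderScene <- function(spec) {
  validObject(spec)
  geo <- sceneGeometry(spec)
  par <- sampleSceneParams(spec)
  cfg <- ThresholdConfig()
  W <- geo$width; H <- geo$height
  nPot <- spec@rows * spec@cols
  scale <- rep_len(spec@plantScale, nPot)
  hues <- rep_len(spec@plantHues, nPot)

  img <- array(0, dim = c(H, W, 3))
  masks <- list()
  boxes <- list()

  withSeed(spec@noiseSeed, {
    bg <- par$bgGray + roundHalfUp(runif(H * W, -5, 5))
    for (ch in 1:3) img[, , ch] <- bg

    potIdx <- 0L
    allPots <- c(lapply(seq_len(nPot), function(i) {
      row <- (i - 1L) %/% spec@cols + 1L
      col <- (i - 1L) %% spec@cols + 1L
      list(kind = "pot", i = i, row = row, col = col,
           cx = geo$potX[col], cy = geo$potY[row], s = scale[i], hue = hues[i])
    }), lapply(seq_along(geo$decoyXY), function(k) {
      list(kind = "decoy", i = nPot + k, row = NA, col = NA,
           cx = geo$decoyXY[[k]]["x"], cy = geo$decoyXY[[k]]["y"],
           s = mean(scale), hue = mean(hues))
    }))

    for (p in allPots) {
      if (p$kind == "pot" && p$i %in% spec@emptyPots) next
      pp <- par$potPar[[p$i]]
      # plate: dark disk, neutral gray with small jitter
      R <- spec@plateRadius
      xs <- max(1L, floor(p$cx - R)):min(W, ceiling(p$cx + R))
      ys <- max(1L, floor(p$cy - R)):min(H, ceiling(p$cy + R))
      dd <- outer((ys - p$cy)^2, rep(1, length(xs))) +
            outer(rep(1, length(ys)), (xs - p$cx)^2)
      disk <- dd <= R^2
      shade <- pp$plateShade + roundHalfUp(runif(sum(disk), -4, 4))
      for (ch in 1:3) {
        plane <- img[ys, xs, ch]
        plane[disk] <- shade
        img[ys, xs, ch] <- plane
      }
      # plant
      m <- rasterizePlant(pp, p$cx, p$cy, spec@plantRadius * p$s, W, H)
      px <- samplePlantColors(sum(m == 1L), p$hue, cfg)
      sel <- which(m == 1L)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[sel] <- px[, ch]
        img[, , ch] <- plane
      }
      if (p$kind == "pot") {
        masks[[sprintf("r%dc%d", p$row, p$col)]] <- m
      }
      boxes[[length(boxes) + 1L]] <- data.frame(
        label = "POT",
        x0 = floor(p$cx - R) - 1, y0 = floor(p$cy - R) - 1,
        x1 = ceiling(p$cx + R) + 1, y1 = ceiling(p$cy + R) + 1,
        score = 1, kind = p$kind, stringsAsFactors = FALSE)
    }
  })

  # QR fiducial: white square with black modules in the central 72%,
  # topped up deterministically so the black fraction is at least 30%
  # (keeps the white-reference percentile rule well defined).
  q <- geo$qrSize
  qx0 <- round(geo$qrCenter[1] - q / 2); qy0 <- round(geo$qrCenter[2] - q / 2)
  xs <- (qx0 + 1):(qx0 + q); ys <- (qy0 + 1):(qy0 + q)
  for (ch in 1:3) img[ys, xs, ch] <- 255
  mreg <- round(0.72 * q)
  m0 <- floor((q - mreg) / 2)
  cell <- mreg / 7
  black <- matrix(FALSE, q, q)
  for (mi in 1:7) for (mj in 1:7) {
    if (!par$qrPattern[mi, mj]) next
    yy <- (m0 + ceiling((mi - 1) * cell + 1)):(m0 + floor(mi * cell))
    xx <- (m0 + ceiling((mj - 1) * cell + 1)):(m0 + floor(mj * cell))
    if (length(yy) && length(xx)) black[yy, xx] <- TRUE
  }
  need <- ceiling(0.30 * q * q) - sum(black)
  if (need > 0) {
    inner <- which(!black &
      row(black) > m0 & row(black) <= m0 + mreg &
      col(black) > m0 & col(black) <= m0 + mreg)
    ord <- order((inner * 2654435761) %% 4294967296)  # deterministic shuffle
    black[inner[ord][seq_len(min(need, length(inner)))]] <- TRUE
  }
  for (ch in 1:3) {
    plane <- img[ys, xs, ch]
    plane[black] <- 10
    img[ys, xs, ch] <- plane
  }
  boxes[[length(boxes) + 1L]] <- data.frame(
    label = "QRCODE", x0 = qx0 - 1, y0 = qy0 - 1,
    x1 = qx0 + q + 1, y1 = qy0 + q + 1, score = 1, kind = "qr",
    stringsAsFactors = FALSE)

  if (any(spec@colorCast != 1))
    img <- applyColorCast(img, spec@colorCast) else storage.mode(img) <- "integer"

  allBoxes <- do.call(rbind, boxes)
  truthBoxes <- allBoxes[allBoxes$kind != "decoy", names(allBoxes) != "kind"]
  decoyBoxes <- allBoxes[allBoxes$kind == "decoy", names(allBoxes) != "kind"]
  rownames(truthBoxes) <- rownames(decoyBoxes) <- NULL

  nonEmpty <- setdiff(seq_len(nPot), spec@emptyPots)
  barcodes <- sprintf("P%02d", seq_len(nPot))

  new("SceneBundle", image = img, truthMasks = masks,
      truthBoxes = truthBoxes, decoyBoxes = decoyBoxes,
      barcodes = barcodes, spec = spec)
}

#' Apply a multiplicative color cast
#'
#' Multiplies each channel of an 8-bit RGB image by a positive gain,
#' clipping to \[0, 255\] and rounding half up. The inverse operation is
#' white balancing against a reference estimated on the cast image
#' ([estimateWhite()] + [whiteBalance()]).
#'
#' @param image integer RGB array (height x width x 3, 0..255).
#' @param gains numeric length-3 positive per-channel gains.
#' @return cast image, same shape, integer 0..255.
#' @export
applyColorCast <- function(image, gains) {
  stopIfNot8bitRGB(image)
  if (length(gains) != 3L || any(gains <= 0)) stop("gains must be 3 positive values")
  out <- image
  for (ch in 1:3) out[, , ch] <- clip255(roundHalfUp(image[, , ch] * gains[ch]))
  storage.mode(out) <- "integer"
  out
}

#' Render a longitudinal series of scenes
#'
#' Renders `days` x `imagesPerDay` captures of one scene. Scene geometry is
#' fixed across the series (seeded once); per-pot plant scale grows so the
#' truth mask area increases by about `areaGrowthPerDay` pixels per day
#' (capped so plants never overflow their plates), the nominal hue drifts
#' linearly by `hueDriftPerDay` degrees per day, and only the per-pixel
#' color noise differs between captures. Capture times are evenly spaced in
#' 10:00-17:00 (14 images per day reproduces the half-hour schedule) and
#' filenames follow `<cameraId>_MT%Y%m%d%H%M%S.png`.
#'
#' @param spec base [SceneSpec-class] (day-0 state).
#' @param days number of days (>= 1); day indices run 0..days-1.
#' @param areaGrowthPerDay target truth-area increase, pixels/day.
#' @param hueDriftPerDay linear hue drift, degrees/day.
#' @param imagesPerDay captures per day (>= 1).
#' @param cameraId camera identifier embedded in filenames.
#' @param startDate calendar date of day 0.
#' @param dir if non-NULL, PNG images (plus a `truth.csv` ground-truth table
#'   and `manifest.csv`) are written there and bundles are not kept in
#'   memory.
#' @return a list with `manifest` (one row per image: filename, day,
#'   timestamp), `truth` (one row per image x pot: truth area in pixels and
#'   nominal hue), and, when `dir` is NULL, `bundles` (list of
#'   [SceneBundle-class]).
#' @export
renderSeries <- function(spec, days, areaGrowthPerDay = 10, hueDriftPerDay = 2,
                         imagesPerDay = 14L, cameraId = "cam001",
                         startDate = as.Date("2019-03-01"), dir = NULL) {
  stopifnot(days >= 1, imagesPerDay >= 1)
  validObject(spec)
  nPot <- spec@rows * spec@cols
  par <- sampleSceneParams(spec)
  geo <- sceneGeometry(spec)
  baseScale <- rep_len(spec@plantScale, nPot)
  baseHues <- rep_len(spec@plantHues, nPot)

  # day-0 truth areas per pot, from the same rasterizer used for rendering
  a0 <- vapply(seq_len(nPot), function(i) {
    if (i %in% spec@emptyPots) return(NA_real_)
    row <- (i - 1L) %/% spec@cols + 1L; col <- (i - 1L) %% spec@cols + 1L
    sum(rasterizePlant(par$potPar[[i]], geo$potX[col], geo$potY[row],
                       spec@plantRadius * baseScale[i], geo$width, geo$height))
  }, numeric(1))
  maxUnit <- vapply(par$potPar[seq_len(nPot)],
                    function(pp) max(pp$rho + pp$aRad), numeric(1))
  sCap <- pmin((spec@plateRadius - 1) / (maxUnit * spec@plantRadius),
               spec@plateRadius / (1.15 * spec@plantRadius) * 0.999)

  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  secs <- (seq_len(imagesPerDay) - 1L) * (7 * 3600) %/% imagesPerDay
  bundles <- list(); manifest <- list(); truth <- list()

  for (d in seq_len(days) - 1L) {
    sDay <- pmin(baseScale * sqrt((a0 + d * areaGrowthPerDay) / a0), sCap)
    sDay[is.na(sDay)] <- 1
    hDay <- pmin(pmax(baseHues + d * hueDriftPerDay, 0), 359.9)
    for (k in seq_len(imagesPerDay)) {
      ts <- as.POSIXct(startDate, tz = "UTC") + d * 86400 + 10 * 3600 + secs[k]
      fname <- imageFilename(cameraId, ts)
      sp <- spec
      sp@plantScale <- sDay
      sp@plantHues <- hDay
      sp@noiseSeed <- as.integer((spec@seed * 1009 + d * 997 + k * 13) %% 2147483647)
      bundle <- renderScene(sp)
      areas <- vapply(seq_len(nPot), function(i) {
        key <- sprintf("r%dc%d", (i - 1L) %/% spec@cols + 1L,
                       (i - 1L) %% spec@cols + 1L)
        if (is.null(bundle@truthMasks[[key]])) NA_real_
        else sum(bundle@truthMasks[[key]])
      }, numeric(1))
      truth[[length(truth) + 1L]] <- data.frame(
        filename = fname, day = d, pot = seq_len(nPot),
        barcode = bundle@barcodes, truthArea = areas, truthHue = hDay,
        stringsAsFactors = FALSE)
      manifest[[length(manifest) + 1L]] <- data.frame(
        filename = fname, day = d,
        timestamp = format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
        stringsAsFactors = FALSE)
      if (is.null(dir)) bundles[[fname]] <- bundle
      else png::writePNG(sceneImage(bundle) / 255, file.path(dir, fname))
    }
  }
  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truth)
  if (!is.null(dir)) {
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  out <- list(manifest = manifest, truth = truth, dir = dir)
  if (is.null(dir)) out$bundles <- bundles
  out
}

#' Accessors for rendered scenes
#'
#' @param bundle a [SceneBundle-class].
#' @return `sceneImage()` the integer RGB array; `truthMasks()` the named
#'   list of 0/1 matrices; `truthBoxes()` the truth detection boxes.
#' @export
sceneImage <- function(bundle) bundle@image

#' @rdname sceneImage
#' @export
truthMasks <- function(bundle) bundle@truthMasks

#' @rdname sceneImage
#' @export
truthBoxes <- function(bundle) bundle@truthBoxes

#' Write a rendered scene to disk
#'
#' Writes the image as PNG, each truth mask as a 0/255 PNG, and the truth
#' boxes plus barcodes as a JSON sidecar.
#'
#' @param bundle a [SceneBundle-class].
#' @param dir output directory (created if missing).
#' @param basename file stem (default "scene").
#' @return invisibly, the paths written.
#' @export
writeScene <- function(bundle, dir, basename = "scene") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(basename, ".png"))
  png::writePNG(bundle@image / 255, paths)
  for (nm in names(bundle@truthMasks)) {
    p <- file.path(dir, sprintf("%s_mask_%s.png", basename, nm))
    png::writePNG(bundle@truthMasks[[nm]], p)
    paths <- c(paths, p)
  }
  side <- file.path(dir, paste0(basename, ".json"))
  jsonlite::write_json(list(boxes = bundle@truthBoxes,
                            barcodes = bundle@barcodes),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, side))
}

#' Camera map and ID map for a synthetic scene
#'
#' Builds the two lookup tables the pipeline needs for a synthetic scene:
#' a camera map tying the camera to a `rows x cols` block of NS/EW
#' coordinates (orientation 0), and an ID map tying each coordinate to the
#' scene's per-pot barcode.
#'
#' @param spec a [SceneSpec-class].
#' @param cameraId camera identifier (default "cam001").
#' @return list with `cameraMap` and `idMap` data.frames in the CSV layouts
#'   read by [readCameraMap()] and [readIdMap()].
#' @export
sceneMaps <- function(spec, cameraId = "cam001") {
  nPot <- spec@rows * spec@cols
  idx <- seq_len(nPot) - 1L
  idMap <- data.frame(barcode = sprintf("P%02d", idx + 1L),
                      ns = idx %/% spec@cols, ew = idx %% spec@cols,
                      stringsAsFactors = FALSE)
  cameraMap <- data.frame(camera_id = cameraId,
                          ns_min = 0L, ns_max = spec@rows - 1L,
                          ew_min = 0L, ew_max = spec@cols - 1L,
                          orientation = 0L, stringsAsFactors = FALSE)
  list(cameraMap = cameraMap, idMap = idMap)
}

#' @describeIn SceneSpec-class compact display
#' @param object a SceneSpec
#' @export
setMethod("show", "SceneSpec", function(object) {
  geo <- sceneGeometry(object)
  cat(sprintf("SceneSpec: %d x %d pots, image %d x %d px, %d empty, %d decoys, seed %d\n",
              object@rows, object@cols, geo$width, geo$height,
              length(object@emptyPots), object@extraPots, object@seed))
})

#' @describeIn SceneBundle-class compact display
#' @param object a SceneBundle
#' @export
setMethod("show", "SceneBundle", function(object) {
  d <- dim(object@image)
  cat(sprintf("SceneBundle: %d x %d px, %d truth masks, %d truth boxes (%s)\n",
              d[2], d[1], length(object@truthMasks), nrow(object@truthBoxes),
              paste(table(object@truthBoxes$label), collapse = " POT + ")))
})
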