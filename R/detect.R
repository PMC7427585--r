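# Plant location detection and grouping. The neural detector is pluggable
# (any function image -> box table); a reference detector for synthetic
# scenes finds plates by dark-disk response and the QR fiducial by
# white-square response. Group selection clusters pot boxes into rows,
# enumerates contiguous windows of cols columns over adjacent rows, keeps
# windows whose hull contains the QR center, and returns the one whose
# centroid is nearest the QR.

#' Construct a detection box table
#'
#' Validated constructor for the plain data.frame representation of labeled
#' candidate rectangles: one row per box with `label` (POT, QRCODE or
#' QRCOLOR), 0-based half-open pixel coordinates `x0 < x1`, `y0 < y1`, and a
#' confidence `score` in \[0, 1\].
#'
#' @param label,x0,y0,x1,y1,score vectors of equal length.
#' @return data.frame of boxes sorted by descending score.
#' @export
detectionBoxes <- function(label, x0, y0, x1, y1, score = 1) {
  df <- data.frame(label = as.character(label),
                   x0 = as.numeric(x0), y0 = as.numeric(y0),
                   x1 = as.numeric(x1), y1 = as.numeric(y1),
                   score = as.numeric(rep_len(score, length(label))),
                   stringsAsFactors = FALSE)
  if (!all(df$label %in% c("POT", "QRCODE", "QRCOLOR")))
    stop("label must be POT, QRCODE or QRCOLOR")
  if (any(df$x0 >= df$x1) || any(df$y0 >= df$y1))
    stop("boxes must satisfy x0 < x1 and y0 < y1")
  if (any(df$score < 0) || any(df$score > 1))
    stop("scores must lie in [0, 1]")
  df <- df[order(-df$score), , drop = FALSE]
  rownames(df) <- NULL
  df
}

emptyBoxes <- function() {
  data.frame(label = character(), x0 = numeric(), y0 = numeric(),
             x1 = numeric(), y1 = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Intersection over union of two boxes
#'
#' @param a,b numeric boxes (x0, y0, x1, y1), 0-based half-open.
#' @return IoU in \[0, 1\].
#' @export
boxIoU <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (union <= 0) 0 else inter / union
}

# Bounding boxes of connected components of a logical matrix.
# Returns a data.frame in 0-based half-open coordinates.
componentBoxes <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0) return(data.frame(x0 = numeric(), y0 = numeric(),
                                x1 = numeric(), y1 = numeric(),
                                area = numeric()))
  idx <- which(lab > 0)
  comp <- lab[idx]
  rowi <- (idx - 1) %% nrow(mask) + 1
  coli <- (idx - 1) %/% nrow(mask) + 1
  data.frame(
    x0 = tapply(coli, comp, min) - 1, y0 = tapply(rowi, comp, min) - 1,
    x1 = tapply(coli, comp, max), y1 = tapply(rowi, comp, max),
    area = as.numeric(table(comp)))
}

#' Reference detector for synthetic scenes
#'
#' Finds plates by dark-disk response (connected regions darker than 22% of
#' the image's bright quantile, roughly square and large enough) and the QR
#' fiducial by white-square response (the brightest, squarest region that
#' contains dark module pixels). Thresholds are relative to the 99.9%
#' brightness quantile so detection also works on images with a
#' multiplicative color cast, since detection runs before color correction.
#'
#' @param image 8-bit RGB array.
#' @param minArea minimum component pixel area considered (default 40).
#' @return detection box data.frame (see [detectionBoxes()]), sorted by
#'   descending score; empty for a blank image.
#' @export
referenceDetector <- function(image, minArea = 40) {
  d <- stopIfNot8bitRGB(image)
  v <- pmax(image[, , 1], image[, , 2], image[, , 3])
  vref <- as.numeric(quantile(v, 0.999))
  if (vref <= 0) return(emptyBoxes())
  out <- list()

  dark <- componentBoxes(v < 0.22 * vref)
  dark <- dark[dark$area >= minArea, , drop = FALSE]
  if (nrow(dark)) {
    w <- dark$x1 - dark$x0; h <- dark$y1 - dark$y0
    ar <- pmin(w / h, h / w)
    fill <- dark$area / (w * h)
    keep <- ar >= 0.5 & w >= 6 & h >= 6
    dark <- dark[keep, , drop = FALSE]
    if (nrow(dark))
      out$pots <- data.frame(label = "POT", x0 = dark$x0, y0 = dark$y0,
                             x1 = dark$x1, y1 = dark$y1,
                             score = pmin(1, 0.5 + 0.5 * ar[keep] * pmin(1, fill[keep] / 0.7)),
                             stringsAsFactors = FALSE)
  }

  white <- componentBoxes(v >= 0.93 * vref)
  if (nrow(white)) {
    w <- white$x1 - white$x0; h <- white$y1 - white$y0
    ar <- pmin(w / h, h / w)
    keep <- white$area >= max(minArea, 60) & ar >= 0.6
    white <- white[keep, , drop = FALSE]; ar <- ar[keep]
    if (nrow(white)) {
      hasDark <- vapply(seq_len(nrow(white)), function(i) {
        sub <- v[(white$y0[i] + 1):white$y1[i], (white$x0[i] + 1):white$x1[i]]
        mean(sub < 0.35 * vref) > 0.05
      }, logical(1))
      white <- white[hasDark, , drop = FALSE]; ar <- ar[hasDark]
      if (nrow(white)) {
        best <- order(-ar, -white$area)[1]
        out$qr <- data.frame(label = "QRCODE",
                             x0 = white$x0[best], y0 = white$y0[best],
                             x1 = white$x1[best], y1 = white$y1[best],
                             score = ar[best], stringsAsFactors = FALSE)
      }
    }
  }
  # the QR's black modules form a small dark blob; never report it as a pot
  if (!is.null(out$qr) && !is.null(out$pots)) {
    cx <- (out$pots$x0 + out$pots$x1) / 2
    cy <- (out$pots$y0 + out$pots$y1) / 2
    inQr <- cx >= out$qr$x0 & cx <= out$qr$x1 & cy >= out$qr$y0 & cy <= out$qr$y1
    out$pots <- out$pots[!inQr, , drop = FALSE]
    if (!nrow(out$pots)) out$pots <- NULL
  }
  if (!length(out)) return(emptyBoxes())
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[order(-df$score), , drop = FALSE]
}

#' Detect candidate boxes on an image
#'
#' Runs a pluggable detector (any function image -> detection box table)
#' and returns its candidates sorted by descending score. Detector failures
#' are propagated with the image identity attached.
#'
#' @param image 8-bit RGB array.
#' @param detector detector function (default [referenceDetector()]).
#' @param imageId identity used in error messages (default "<image>").
#' @return detection box data.frame sorted by descending score.
#' @export
detectCandidates <- function(image, detector = referenceDetector,
                             imageId = "<image>") {
  boxes <- tryCatch(detector(image), error = function(e)
    pgError("pgDetectorError",
            sprintf("detector failed on %s: %s", imageId, conditionMessage(e))))
  boxes[order(-boxes$score), , drop = FALSE]
}

# 1-D gap clustering: split sorted centers where consecutive gaps exceed
# the threshold. Returns a cluster index per (unsorted) input element.
gapCluster <- function(centers, gap) {
  ord <- order(centers)
  cl <- integer(length(centers))
  cur <- 1L
  cl[ord[1]] <- cur
  if (length(centers) > 1) for (i in 2:length(ord)) {
    if (centers[ord[i]] - centers[ord[i - 1]] > gap) cur <- cur + 1L
    cl[ord[i]] <- cur
  }
  cl
}

#' Select the group of pots anchored by the QR code
#'
#' Clusters POT candidates into rows by box-center vertical coordinate
#' (1-D gap clustering with the median box height as gap threshold), sorts
#' each row by horizontal center, clusters the boxes of each run of `rows`
#' adjacent rows into columns, and enumerates all contiguous `cols`-wide
#' windows. A window is admissible when the QRCODE center lies inside the
#' window's bounding hull; among admissible windows the one whose centroid
#' is nearest the QR center wins. Grid positions without a detected pot
#' (empty pots) are flagged `present = FALSE`.
#'
#' @param candidates detection box data.frame; QRCOLOR boxes are ignored.
#' @param rows,cols group layout (default 2 x 5).
#' @return a [PlantGroup-class] with members in row-major order.
#' @section Errors: `pgQrNotFound` when no QRCODE candidate exists;
#'   `pgGroupNotFound` when no admissible window exists. Both drive the
#'   missing-plant accounting of the batch pipeline.
#' @export
selectGroup <- function(candidates, rows = 2L, cols = 5L) {
  qrs <- candidates[candidates$label == "QRCODE", , drop = FALSE]
  if (!nrow(qrs)) pgError("pgQrNotFound", "QR not found")
  qr <- as.numeric(qrs[which.max(qrs$score), c("x0", "y0", "x1", "y1")])
  qc <- c((qr[1] + qr[3]) / 2, (qr[2] + qr[4]) / 2)

  pots <- candidates[candidates$label == "POT", , drop = FALSE]
  if (nrow(pots) < rows) pgError("pgGroupNotFound", "group not identified")
  yc <- (pots$y0 + pots$y1) / 2
  xc <- (pots$x0 + pots$x1) / 2
  rowCl <- gapCluster(yc, gap = median(pots$y1 - pots$y0))
  rowOrder <- order(tapply(yc, rowCl, mean))
  nRows <- length(rowOrder)
  if (nRows < rows) pgError("pgGroupNotFound", "group not identified")

  best <- NULL
  for (r0 in seq_len(nRows - rows + 1L)) {
    rowSet <- rowOrder[r0:(r0 + rows - 1L)]
    sel <- rowCl %in% rowSet
    sub <- pots[sel, , drop = FALSE]
    subRow <- match(rowCl[sel], rowSet)      # 1..rows, top to bottom
    subX <- xc[sel]
    colCl <- gapCluster(subX, gap = median(sub$x1 - sub$x0))
    colOrder <- order(tapply(subX, colCl, mean))
    nCols <- length(colOrder)
    if (nCols < cols) next
    for (c0 in seq_len(nCols - cols + 1L)) {
      colSet <- colOrder[c0:(c0 + cols - 1L)]
      grid <- vector("list", rows * cols)
      for (i in seq_len(nrow(sub))) {
        gc <- match(colCl[i], colSet)
        if (is.na(gc)) next
        pos <- (subRow[i] - 1L) * cols + gc
        if (is.null(grid[[pos]]) || sub$score[i] > grid[[pos]]$score)
          grid[[pos]] <- sub[i, ]
      }
      memb <- do.call(rbind, grid[!vapply(grid, is.null, logical(1))])
      if (is.null(memb) || nrow(memb) < 2) next
      hull <- c(min(memb$x0), min(memb$y0), max(memb$x1), max(memb$y1))
      if (qc[1] < hull[1] || qc[1] > hull[3] ||
          qc[2] < hull[2] || qc[2] > hull[4]) next
      centroid <- c(mean((memb$x0 + memb$x1) / 2), mean((memb$y0 + memb$y1) / 2))
      dist <- sqrt(sum((centroid - qc)^2))
      if (is.null(best) || dist < best$dist)
        best <- list(dist = dist, grid = grid)
    }
  }
  if (is.null(best)) pgError("pgGroupNotFound", "group not identified")

  members <- do.call(rbind, lapply(seq_len(rows * cols), function(pos) {
    b <- best$grid[[pos]]
    data.frame(row = (pos - 1L) %/% cols + 1L, col = (pos - 1L) %% cols + 1L,
               x0 = if (is.null(b)) NA_real_ else b$x0,
               y0 = if (is.null(b)) NA_real_ else b$y0,
               x1 = if (is.null(b)) NA_real_ else b$x1,
               y1 = if (is.null(b)) NA_real_ else b$y1,
               score = if (is.null(b)) NA_real_ else b$score,
               present = !is.null(b), stringsAsFactors = FALSE)
  }))
  new("PlantGroup", members = members, qr = qr,
      rows = as.integer(rows), cols = as.integer(cols))
}

#' Read camera map and ID map tables
#'
#' The camera map ties each camera to a block of NS/EW greenhouse
#' coordinates and the camera's orientation relative to the NS/EW axes
#' (columns: camera_id, ns_min, ns_max, ew_min, ew_max, orientation). The
#' ID map ties each coordinate to a pot barcode (columns: barcode, ns, ew).
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readCameraMap <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("camera_id", "ns_min", "ns_max", "ew_min", "ew_max", "orientation")
  if (!all(need %in% names(df)))
    stop("camera map must have columns ", paste(need, collapse = ", "))
  if (!all(df$orientation %in% c(0L, 90L, 180L, 270L)))
    stop("orientation must be one of 0, 90, 180, 270")
  df
}

#' @rdname readCameraMap
#' @export
readIdMap <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "ns", "ew") %in% names(df)))
    stop("ID map must have columns barcode, ns, ew")
  if (anyDuplicated(df$barcode) || anyDuplicated(df[c("ns", "ew")]))
    stop("barcodes and coordinates must be unique")
  df
}

# Rotate an image-grid position (r, c) in a R x C grid by the camera
# orientation into 0-based block-internal (ns, ew) offsets.
orientGrid <- function(r, c, R, C, orientation) {
  switch(as.character(orientation),
    "0"   = c(ns = r, ew = c),
    "90"  = c(ns = c, ew = R - 1L - r),
    "180" = c(ns = R - 1L - r, ew = C - 1L - c),
    "270" = c(ns = C - 1L - c, ew = r),
    stop("orientation must be one of 0, 90, 180, 270"))
}

#' Assign barcodes to a selected group
#'
#' Rotates each member's grid position by the camera's orientation into an
#' (ns, ew) coordinate inside the camera's block and attaches the barcode
#' the ID map holds for that coordinate. The mapping is a bijection between
#' grid positions and the block's 10 coordinates.
#'
#' @param group a [PlantGroup-class].
#' @param cam one row of a camera map (list or single-row data.frame with
#'   ns_min, ns_max, ew_min, ew_max, orientation).
#' @param idMap ID map data.frame (barcode, ns, ew).
#' @return the group with `ns`, `ew` and `barcode` columns filled in.
#' @section Errors: `pgUnmappedCoordinate` when the ID map lacks an entry
#'   for one of the block's coordinates.
#' @export
assignBarcodes <- function(group, cam, idMap) {
  R <- group@rows; C <- group@cols
  nsSize <- cam$ns_max - cam$ns_min + 1L
  ewSize <- cam$ew_max - cam$ew_min + 1L
  need <- if (cam$orientation %in% c(0L, 180L)) c(R, C) else c(C, R)
  if (nsSize != need[1] || ewSize != need[2])
    stop(sprintf("camera block %d x %d does not match grid %d x %d at orientation %d",
                 nsSize, ewSize, R, C, cam$orientation))
  m <- group@members
  coords <- t(vapply(seq_len(nrow(m)), function(i)
    orientGrid(m$row[i] - 1L, m$col[i] - 1L, R, C, cam$orientation),
    c(ns = 0, ew = 0)))
  m$ns <- cam$ns_min + coords[, "ns"]
  m$ew <- cam$ew_min + coords[, "ew"]
  key <- paste(m$ns, m$ew)
  hit <- match(key, paste(idMap$ns, idMap$ew))
  if (anyNA(hit))
    pgError("pgUnmappedCoordinate",
            sprintf("unmapped coordinate (ns %s, ew %s)",
                    m$ns[which(is.na(hit))[1]], m$ew[which(is.na(hit))[1]]))
  m$barcode <- idMap$barcode[hit]
  group@members <- m
  group
}

#' Crop fixed-size windows around each group member
#'
#' Each crop is `cropSize x cropSize`, centered on the member box center;
#' regions outside the image are zero-padded so all crops have identical
#' dimensions, keeping area measurements comparable between pots. Members
#' without a detected box give NULL.
#'
#' @param image 8-bit RGB array.
#' @param group a [PlantGroup-class].
#' @param cropSize crop side in pixels (even; default 512).
#' @return list of `rows * cols` crops (integer arrays or NULL), row-major.
#' @export
cropPots <- function(image, group, cropSize = 512L) {
  d <- stopIfNot8bitRGB(image)
  half <- cropSize %/% 2L
  lapply(seq_len(nrow(group@members)), function(i) {
    m <- group@members[i, ]
    if (!m$present) return(NULL)
    cx <- floor((m$x0 + m$x1) / 2); cy <- floor((m$y0 + m$y1) / 2)
    out <- array(0L, c(cropSize, cropSize, 3L))
    xs <- (cx - half):(cx + half - 1L)   # 0-based target columns
    ys <- (cy - half):(cy + half - 1L)
    okx <- xs >= 0 & xs < d[2]; oky <- ys >= 0 & ys < d[1]
    out[which(oky), which(okx), ] <- image[ys[oky] + 1L, xs[okx] + 1L, , drop = FALSE]
    out
  })
}

#' Read and write detection boxes as JSON
#'
#' The JSON layout is a list of objects with fields label, x0, y0, x1, y1,
#' score.
#'
#' @param boxes detection box data.frame.
#' @param path JSON file.
#' @return `readDetections()` returns the box data.frame.
#' @export
writeDetections <- function(boxes, path) {
  jsonlite::write_json(boxes, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeDetections
#' @export
readDetections <- function(path) {
  df <- jsonlite::fromJSON(path)
  detectionBoxes(df$label, df$x0, df$y0, df$x1, df$y1, df$score)
}

#' @describeIn PlantGroup-class compact display
#' @param object a PlantGroup
#' @export
setMethod("show", "PlantGroup", function(object) {
  cat(sprintf("PlantGroup: %d x %d grid, %d/%d pots present%s\n",
              object@rows, object@cols, sum(object@members$present),
              nrow(object@members),
              if ("barcode" %in% names(object@members)) ", barcodes assigned" else ""))
})
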