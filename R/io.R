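# Filename conventions, pipeline configuration, batch execution and
# concurrency-safe result output. Filenames embed the camera ID and a
# timestamp as "<camera_id>_MT%Y%m%d%H%M%S.<ext>"; the fixed-width
# timestamp makes lexicographic order equal chronological order per
# camera. Appends to shared CSVs go through an exclusive lock so rows from
# concurrent workers never interleave or vanish.

#' Parse an image filename into camera ID and timestamp
#'
#' Filenames follow `<camera_id>_MT%Y%m%d%H%M%S.<ext>`. Lexicographic
#' filename order equals chronological order per camera because the
#' timestamp digits are fixed-width.
#'
#' @param name filename (basename; any directory part is stripped).
#' @return list with `cameraId` (character) and `timestamp` (POSIXct, UTC).
#' @section Errors: `pgParseError` naming the offending segment.
#' @examples
#' parseFilename("cam042_MT20190315103000.jpg")
#' @export
parseFilename <- function(name) {
  base <- basename(name)
  stem <- sub("\\.[A-Za-z0-9]+$", "", base)
  if (!grepl("_MT", stem, fixed = TRUE))
    pgError("pgParseError",
            sprintf("cannot parse '%s': missing '_MT' timestamp token", base))
  cameraId <- sub("_MT.*$", "", stem)
  ts <- sub("^.*_MT", "", stem)
  if (!grepl("^[0-9]{14}$", ts))
    pgError("pgParseError",
            sprintf("cannot parse '%s': timestamp '%s' is not 14 digits", base, ts))
  if (!nzchar(cameraId))
    pgError("pgParseError",
            sprintf("cannot parse '%s': empty camera ID segment", base))
  stamp <- as.POSIXct(strptime(ts, "%Y%m%d%H%M%S", tz = "UTC"))
  if (is.na(stamp) || format(stamp, "%Y%m%d%H%M%S", tz = "UTC") != ts)
    pgError("pgParseError",
            sprintf("cannot parse '%s': invalid timestamp '%s'", base, ts))
  list(cameraId = cameraId, timestamp = stamp)
}

#' Build an image filename from camera ID and timestamp
#'
#' @param cameraId camera identifier (must not contain "_MT").
#' @param timestamp POSIXct capture time (formatted in UTC).
#' @param ext file extension (default "png").
#' @return filename string; round-trips through [parseFilename()].
#' @export
imageFilename <- function(cameraId, timestamp, ext = "png") {
  if (grepl("_MT", cameraId, fixed = TRUE))
    stop("cameraId must not contain '_MT'")
  sprintf("%s_MT%s.%s", cameraId,
          format(timestamp, "%Y%m%d%H%M%S", tz = "UTC"), ext)
}

#' Read an image file as an 8-bit RGB array
#'
#' Grayscale images are expanded to three channels; an alpha channel is
#' dropped.
#'
#' @param path PNG file.
#' @return integer array height x width x 3, values 0..255.
#' @export
readImageRGB <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 2L) m <- array(rep(m, 3), c(dim(m), 3L))
  if (dim(m)[3] > 3L) m <- m[, , 1:3, drop = FALSE]
  out <- roundHalfUp(m * 255)
  storage.mode(out) <- "integer"
  out
}

#' Append rows to a shared file under an exclusive lock
#'
#' Acquires a lock (an atomically created `<file>.lock` directory), appends
#' the lines, and releases the lock, so that under concurrent writers every
#' row appears exactly once and no row interleaves another. Lock
#' acquisition retries with bounded backoff and fails after `timeout`
#' seconds.
#'
#' @param file target path (parent directory created if needed).
#' @param lines character vector of complete rows (no embedded newlines).
#' @param timeout seconds to keep retrying the lock (default 30).
#' @return invisibly TRUE.
#' @export
appendResult <- function(file, lines, timeout = 30) {
  dir <- dirname(file)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lockdir <- paste0(file, ".lock")
  deadline <- Sys.time() + timeout
  repeat {
    if (suppressWarnings(dir.create(lockdir, showWarnings = FALSE))) break
    if (Sys.time() > deadline)
      pgError("pgLockTimeout",
              sprintf("could not acquire lock %s within %g s", lockdir, timeout))
    Sys.sleep(stats::runif(1, 0.001, 0.02))
  }
  on.exit(unlink(lockdir, recursive = TRUE), add = TRUE)
  con <- file(file, open = "a")
  on.exit(close(con), add = TRUE, after = FALSE)
  writeLines(lines, con)
  flush(con)
  invisible(TRUE)
}

#' Pipeline configuration
#'
#' Bundles everything the batch pipeline needs: the camera and ID maps,
#' detector choice, segmentation thresholds, optional U-net model path,
#' crop size, output directory and layout, and worker count.
#'
#' @param cameraMap camera map data.frame or CSV path ([readCameraMap()]).
#' @param idMap ID map data.frame or CSV path ([readIdMap()]).
#' @param outputDir directory for result CSVs (created on demand).
#' @param cropSize crop side in pixels (default 512).
#' @param thresholds a [ThresholdConfig-class].
#' @param detector "reference" (the synthetic-scene detector) or a function
#'   image -> boxes.
#' @param unetModelPath optional path to a saved [UNetModel-class]; when
#'   set, segmentation uses the U-net in a three-pass run.
#' @param layout subdirectory layout for saved crops: "time" or "id".
#' @param workers number of parallel workers (images are parallelized,
#'   never the work within one image).
#' @param saveCrops also write per-pot crop and mask PNGs.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(cameraMap, idMap, outputDir,
                           cropSize = 512L, thresholds = ThresholdConfig(),
                           detector = "reference", unetModelPath = NULL,
                           layout = c("time", "id"), workers = 1L,
                           saveCrops = FALSE) {
  if (is.character(cameraMap)) cameraMap <- readCameraMap(cameraMap)
  if (is.character(idMap)) idMap <- readIdMap(idMap)
  layout <- match.arg(layout)
  if (workers < 1L) stop("workers must be >= 1")
  if (!is.null(unetModelPath) && !file.exists(unetModelPath))
    stop("unetModelPath does not exist: ", unetModelPath)
  structure(list(cameraMap = cameraMap, idMap = idMap,
                 outputDir = outputDir, cropSize = as.integer(cropSize),
                 thresholds = thresholds, detector = detector,
                 unetModelPath = unetModelPath, layout = layout,
                 workers = as.integer(workers), saveCrops = saveCrops),
            class = "PipelineConfig")
}

#' Read and write a pipeline configuration file
#'
#' The configuration is stored as YAML with paths to the camera and ID map
#' CSVs and scalar settings; threshold bounds are stored inline.
#'
#' @param path YAML file.
#' @param config a `PipelineConfig`.
#' @param cameraMapPath,idMapPath CSV paths recorded in the file.
#' @return `readPipelineConfig()` returns a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- do.call(ThresholdConfig, as.list(y$thresholds %||% list()))
  pipelineConfig(cameraMap = y$camera_map, idMap = y$id_map,
                 outputDir = y$output_dir %||% ".",
                 cropSize = y$crop_size %||% 512L, thresholds = thr,
                 detector = y$detector %||% "reference",
                 unetModelPath = y$unet_model,
                 layout = y$layout %||% "time",
                 workers = y$workers %||% 1L,
                 saveCrops = isTRUE(y$save_crops))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path, cameraMapPath, idMapPath) {
  thr <- config$thresholds
  yaml::write_yaml(list(
    camera_map = cameraMapPath, id_map = idMapPath,
    output_dir = config$outputDir, crop_size = config$cropSize,
    detector = if (is.character(config$detector)) config$detector else "custom",
    unet_model = config$unetModelPath, layout = config$layout,
    workers = config$workers, save_crops = config$saveCrops,
    thresholds = list(hueMin = thr@hueMin, hueMax = thr@hueMax,
                      satMin = thr@satMin, satMax = thr@satMax,
                      valMin = thr@valMin, valMax = thr@valMax,
                      aMin = thr@aMin, aMax = thr@aMax,
                      bMin = thr@bMin, bMax = thr@bMax)), path)
  invisible(path)
}

# Process one image up to crops: detect, group, white-balance, assign
# barcodes, crop. Returns list(meta, crops, barcodes) or signals a pgError.
preprocessImage <- function(path, config) {
  meta <- parseFilename(path)
  image <- readImageRGB(path)
  detector <- if (is.function(config$detector)) config$detector else referenceDetector
  boxes <- detectCandidates(image, detector, imageId = basename(path))
  group <- selectGroup(boxes)
  cam <- config$cameraMap[config$cameraMap$camera_id == meta$cameraId, ]
  if (!nrow(cam))
    pgError("pgCameraUnknown",
            sprintf("camera '%s' not in camera map", meta$cameraId))
  ref <- estimateWhite(image, group@qr)
  balanced <- whiteBalance(image, ref)
  group <- assignBarcodes(group, as.list(cam[1, ]), config$idMap)
  crops <- cropPots(balanced, group, config$cropSize)
  list(meta = meta, group = group, crops = crops, file = basename(path))
}

# Observations for one preprocessed image given its masks.
observeImage <- function(pre, masks, config) {
  m <- pre$group@members
  rows <- lapply(seq_along(pre$crops), function(i) {
    if (is.null(pre$crops[[i]])) return(NULL)
    mask <- masks[[i]]
    sel <- mask == 1L
    hues <- if (any(sel)) {
      px <- flattenRGB(pre$crops[[i]])[as.vector(sel), , drop = FALSE]
      rgbToHsvMat(px)[, "h"]
    } else numeric()
    hs <- hueStats(hueHistogram(hues))
    data.frame(filename = pre$file, camera_id = pre$meta$cameraId,
               timestamp = format(pre$meta$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC"),
               barcode = m$barcode[i], row = m$row[i], col = m$col[i],
               area_px = sum(mask), hue_mean = hs$mean,
               hue_var = hs$variance, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

saveCropOutputs <- function(pre, masks, config) {
  m <- pre$group@members
  tsDir <- format(pre$meta$timestamp, "%Y%m%d%H%M%S", tz = "UTC")
  for (i in seq_along(pre$crops)) {
    if (is.null(pre$crops[[i]])) next
    sub <- if (config$layout == "time") tsDir else m$barcode[i]
    leaf <- if (config$layout == "time") m$barcode[i] else tsDir
    d <- file.path(config$outputDir, "crops", sub)
    if (!dir.exists(d)) dir.create(d, recursive = TRUE, showWarnings = FALSE)
    png::writePNG(pre$crops[[i]] / 255, file.path(d, paste0(leaf, ".png")))
    writeMask(masks[[i]], file.path(d, paste0(leaf, "_mask.png")))
  }
}

areaCols <- c("filename", "camera_id", "timestamp", "barcode", "row", "col",
              "area_px")
greenCols <- c("filename", "camera_id", "timestamp", "barcode", "row", "col",
               "hue_mean", "hue_var")

obsToLines <- function(obs, cols) {
  do.call(paste, c(lapply(obs[cols], function(x)
    trimws(format(x, scientific = FALSE, trim = TRUE))), sep = ","))
}

#' Run the batch image-analysis pipeline
#'
#' For each image: detect candidate boxes, select the QR-anchored group of
#' ten pots, white-balance against the QR white reference, assign barcodes
#' through the camera and ID maps, crop a fixed-size window per pot,
#' segment each crop, and append one observation per pot (projected area in
#' pixels, mean and variance of the plant hue) to `area.csv` and
#' `greenness.csv` in the output directory. Per-image failures (QR not
#' found, group not identified, unknown camera, ...) are logged with their
#' reason and skipped; the run continues.
#'
#' With a U-net model configured the run is split into three passes
#' (preprocess crops to disk, predict masks, postprocess observations) so
#' the prediction pass can be isolated; results are identical to a
#' single-pass run. With `workers > 1` images are processed in parallel;
#' output files are sorted afterwards, so results are identical for any
#' worker count.
#'
#' @param imageFiles paths of images to process.
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @param model optional [UNetModel-class] already in memory (overrides
#'   `config$unetModelPath`).
#' @return invisibly, the observation data.frame (one row per image x pot),
#'   with the failure log in `attr(, "failures")`.
#' @export
runPipeline <- function(imageFiles, config, model = NULL) {
  if (!dir.exists(config$outputDir))
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(model) && !is.null(config$unetModelPath))
    model <- loadUNet(config$unetModelPath)
  areaFile <- file.path(config$outputDir, "area.csv")
  greenFile <- file.path(config$outputDir, "greenness.csv")

  segmentCrops <- function(crops) {
    lapply(crops, function(crop) {
      if (is.null(crop)) return(NULL)
      if (is.null(model)) combinedMask(crop, config$thresholds)
      else predictMask(model, crop)
    })
  }

  worker <- function(path) {
    tryCatch({
      pre <- preprocessImage(path, config)
      masks <- segmentCrops(pre$crops)
      obs <- observeImage(pre, masks, config)
      if (config$saveCrops) saveCropOutputs(pre, masks, config)
      if (!is.null(obs)) {
        appendResult(areaFile, obsToLines(obs, areaCols))
        appendResult(greenFile, obsToLines(obs, greenCols))
      }
      list(ok = TRUE, obs = obs)
    }, pgError = function(e) {
      message(sprintf("[phenogreen] %s: %s", basename(path), conditionMessage(e)))
      list(ok = FALSE, file = basename(path), reason = conditionMessage(e))
    })
  }

  results <- if (config$workers > 1L)
    parallel::mclapply(imageFiles, worker, mc.cores = config$workers)
  else lapply(imageFiles, worker)

  okList <- vapply(results, function(r) isTRUE(r$ok), logical(1))
  obs <- do.call(rbind, lapply(results[okList], `[[`, "obs"))
  failures <- do.call(rbind, lapply(results[!okList], function(r)
    data.frame(file = r$file, reason = r$reason, stringsAsFactors = FALSE)))
  if (is.null(failures))
    failures <- data.frame(file = character(), reason = character(),
                           stringsAsFactors = FALSE)

  # deterministic final files regardless of worker interleaving
  if (!is.null(obs) && nrow(obs)) {
    obs <- obs[order(obs$timestamp, obs$camera_id, obs$barcode), ]
    rownames(obs) <- NULL
    writeLines(c(paste(areaCols, collapse = ","),
                 obsToLines(obs, areaCols)), areaFile)
    writeLines(c(paste(greenCols, collapse = ","),
                 obsToLines(obs, greenCols)), greenFile)
  }
  if (nrow(failures))
    write.csv(failures[order(failures$file), ],
              file.path(config$outputDir, "failures.csv"), row.names = FALSE)
  attr(obs, "failures") <- failures
  invisible(obs)
}

#' Convert pipeline observations to the trait input layout
#'
#' @param obs data.frame from [runPipeline()] or its `area.csv`.
#' @param greenness optional `greenness.csv` data.frame to merge when
#'   `obs` lacks the hue columns (matched on filename and barcode).
#' @return data.frame with plant_id, timestamp, area_px, hue_mean columns
#'   as expected by [dailySummaries()]; hue_mean is NA when no greenness
#'   data is available.
#' @export
asObservations <- function(obs, greenness = NULL) {
  if (is.null(obs$hue_mean) && !is.null(greenness))
    obs <- merge(obs, greenness[, c("filename", "barcode", "hue_mean")],
                 by = c("filename", "barcode"))
  data.frame(plant_id = obs$barcode,
             timestamp = as.POSIXct(obs$timestamp,
                                    format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
             area_px = as.numeric(obs$area_px),
             hue_mean = if (is.null(obs$hue_mean)) NA_real_
                        else as.numeric(obs$hue_mean),
             stringsAsFactors = FALSE)
}
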