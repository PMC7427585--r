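# Camera uptime and throughput accounting: expected image counts from the
# capture schedule, received counts from the filename inventory, and the
# summary table (all / average / worst / best camera). Percentages are kept
# exact internally and rounded half-up only when formatted.

#' Expected image counts for a capture schedule
#'
#' @param days days of operation.
#' @param perDay images taken per day per camera.
#' @param cameras number of cameras.
#' @return list with `perCamera = days * perDay` and
#'   `total = perCamera * cameras`.
#' @examples
#' expectedImages(146, 14, 180)   # 2044 per camera, 367920 total
#' @export
expectedImages <- function(days, perDay, cameras) {
  if (any(c(days, perDay, cameras) <= 0) ||
      any(c(days, perDay, cameras) != floor(c(days, perDay, cameras))))
    stop("days, perDay and cameras must be positive integers")
  perCamera <- days * perDay
  list(perCamera = perCamera, total = perCamera * cameras)
}

#' Uptime percentage
#'
#' Uptime is the number of received images divided by the number expected
#' from the schedule, as a percentage: exact, plus the integer percent
#' (rounded half-up) used for display.
#'
#' @param received images received (>= 0).
#' @param expected images expected (> 0).
#' @return list with `exact` and `rounded`.
#' @examples
#' uptimePct(316790, 367920)$rounded   # 86
#' @export
uptimePct <- function(received, expected) {
  if (expected <= 0) stop("expected must be positive")
  if (received < 0) stop("received must be nonnegative")
  exact <- 100 * received / expected
  list(exact = exact, rounded = as.integer(roundHalfUp(exact)))
}

#' Summarize an image inventory against a capture schedule
#'
#' Parses every filename ([parseFilename()]), counts received images per
#' camera, and compares against the expected counts. Filenames that do not
#' parse are collected separately, never silently dropped.
#'
#' @param filenames character vector of image filenames (basenames).
#' @param operationDays days of operation.
#' @param imagesPerDay scheduled images per day per camera.
#' @param cameras optional character vector of expected camera IDs; by
#'   default the cameras seen in the inventory. Cameras with no images
#'   count as received = 0.
#' @return an [UptimeReport-class].
#' @export
summarizeInventory <- function(filenames, operationDays, imagesPerDay,
                               cameras = NULL) {
  parsed <- lapply(filenames, function(f)
    tryCatch(parseFilename(f), error = function(e) NULL))
  ok <- !vapply(parsed, is.null, logical(1))
  unparseable <- filenames[!ok]
  camIds <- vapply(parsed[ok], `[[`, character(1), "cameraId")
  if (is.null(cameras)) cameras <- sort(unique(camIds))
  counts <- table(factor(camIds, levels = cameras))
  exp <- expectedImages(operationDays, imagesPerDay, max(1L, length(cameras)))
  perCamera <- data.frame(
    cameraId = cameras,
    received = as.numeric(counts),
    uptimePct = vapply(as.numeric(counts),
                       function(r) uptimePct(r, exp$perCamera)$exact,
                       numeric(1)),
    stringsAsFactors = FALSE)
  perCamera <- perCamera[order(perCamera$cameraId), ]
  rownames(perCamera) <- NULL
  received <- sum(perCamera$received)
  new("UptimeReport",
      operationDays = as.integer(operationDays),
      imagesPerDay = as.integer(imagesPerDay),
      nCameras = as.integer(length(cameras)),
      expectedPerCamera = exp$perCamera, expectedTotal = exp$total,
      receivedTotal = received,
      uptimePct = if (exp$total > 0) 100 * received / exp$total else 0,
      perCamera = perCamera, unparseable = unparseable)
}

#' Format an uptime report as a plain-text table
#'
#' Rows: operation time, uptime (integer percent, half-up), pictures
#' (average camera with 2 decimals), expected amount; columns: all cameras,
#' average, worst and best camera. Regeneration on the same inventory is
#' byte-identical (cameras are sorted by ID).
#'
#' @param report an [UptimeReport-class].
#' @return character vector of lines.
#' @export
formatUptimeReport <- function(report) {
  pc <- report@perCamera
  avg <- if (nrow(pc)) report@receivedTotal / nrow(pc) else 0
  worst <- if (nrow(pc)) min(pc$received) else 0
  best <- if (nrow(pc)) max(pc$received) else 0
  fmt <- function(x) formatC(x, format = "f", digits = 2, big.mark = ",")
  fmtI <- function(x) formatC(x, format = "d", big.mark = ",")
  c(sprintf("%-24s %12s %15s %12s %12s", "", "All cameras",
            "Average camera", "Worst", "Best"),
    sprintf("%-24s %12s %15s %12s %12s", "Operation time (days)",
            fmtI(report@operationDays), fmtI(report@operationDays),
            fmtI(report@operationDays), fmtI(report@operationDays)),
    sprintf("%-24s %11d%% %14d%% %11d%% %11d%%", "Uptime (%)",
            as.integer(roundHalfUp(report@uptimePct)),
            as.integer(roundHalfUp(
              if (nrow(pc)) mean(pc$uptimePct) else 0)),
            as.integer(roundHalfUp(
              if (nrow(pc)) min(pc$uptimePct) else 0)),
            as.integer(roundHalfUp(
              if (nrow(pc)) max(pc$uptimePct) else 0))),
    sprintf("%-24s %12s %15s %12s %12s", "Pictures",
            fmtI(report@receivedTotal), fmt(avg), fmtI(worst), fmtI(best)),
    sprintf("%-24s %12s %15s", "Expected amount",
            fmtI(report@expectedTotal), fmtI(report@expectedPerCamera)),
    if (length(report@unparseable))
      sprintf("Unparseable filenames: %d", length(report@unparseable)))
}

#' Write an uptime report
#'
#' Writes the machine-readable JSON and, optionally, the plain-text table.
#' Output is deterministic for a given inventory.
#'
#' @param report an [UptimeReport-class].
#' @param jsonPath JSON output path.
#' @param textPath optional text output path.
#' @return invisibly, the paths written.
#' @export
writeUptimeReport <- function(report, jsonPath, textPath = NULL) {
  jsonlite::write_json(list(
    operation_days = report@operationDays,
    images_per_day = report@imagesPerDay,
    n_cameras = report@nCameras,
    expected_per_camera = report@expectedPerCamera,
    expected_total = report@expectedTotal,
    received_total = report@receivedTotal,
    uptime_pct = report@uptimePct,
    per_camera = report@perCamera,
    unparseable = report@unparseable
  ), jsonPath, auto_unbox = TRUE, digits = NA)
  paths <- jsonPath
  if (!is.null(textPath)) {
    writeLines(formatUptimeReport(report), textPath)
    paths <- c(paths, textPath)
  }
  invisible(paths)
}

#' @describeIn UptimeReport-class compact display
#' @param object an UptimeReport
#' @export
setMethod("show", "UptimeReport", function(object) {
  writeLines(formatUptimeReport(object))
})
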