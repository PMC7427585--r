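# Growth and greenness traits. Per-plant observation streams (projected
# area in pixels and hue statistics per capture) are aggregated into daily
# medians, noisy days are filtered by a variance rule, and two trait
# scalars are derived: AreaPerDay (standardized area under the growth curve
# over a 30-day window, divided by the window length) and RateOfHue (OLS
# slope of the smoothed daily mean hue over the early post-inoculation
# window). Broad-sense heritability partitions trait variance into clover,
# rhizobium and residual components via a delegated mixed-model fit.

#' Hue histogram of masked pixels
#'
#' Counts plant-pixel hues into fixed-width bins covering \[0, 360)
#' degrees. The total count equals the projected plant area.
#'
#' @param hues pixel hues in degrees.
#' @param binWidth bin width in degrees (default 1).
#' @return named numeric vector of counts; names are bin centers.
#' @export
hueHistogram <- function(hues, binWidth = 1) {
  breaks <- seq(0, 360, by = binWidth)
  counts <- tabulate(findInterval(hues %% 360, breaks,
                                  rightmost.closed = FALSE),
                     nbins = length(breaks) - 1L)
  setNames(as.numeric(counts), breaks[-length(breaks)] + binWidth / 2)
}

#' Mean and variance of a hue distribution
#'
#' Arithmetic (non-circular) mean and population variance over pixel hues,
#' with bin centers weighted by counts. Valid because the segmentation mask
#' restricts hues to \[30, 150\] degrees, far from the 0/360 wrap.
#'
#' @param hist named counts from [hueHistogram()] (names = bin centers).
#' @return list with `mean` and `variance` in degrees; both NA (flagged
#'   missing) for an empty histogram.
#' @export
hueStats <- function(hist) {
  n <- sum(hist)
  if (n == 0) return(list(mean = NA_real_, variance = NA_real_, missing = TRUE))
  centers <- as.numeric(names(hist))
  m <- sum(centers * hist) / n
  list(mean = m, variance = sum(hist * (centers - m)^2) / n, missing = FALSE)
}

#' Daily summaries of a plant observation stream
#'
#' Groups observations by plant and calendar date. The daily area is the
#' median of the capture areas (robust to strong outliers from plant
#' movement); the daily variance is the sample variance of those areas
#' (0 for a single capture); the daily hue is the arithmetic mean of the
#' per-capture mean hues.
#'
#' @param obs data.frame with columns `plant_id`, `timestamp` (POSIXct or
#'   parseable), `area_px`, and `hue_mean`.
#' @return data.frame: plant_id, date, median_area, day_variance, mean_hue,
#'   n_obs.
#' @export
dailySummaries <- function(obs) {
  stopifnot(nrow(obs) >= 1)
  date <- as.Date(obs$timestamp, tz = "UTC")
  key <- paste(obs$plant_id, date)
  out <- do.call(rbind, lapply(split(seq_len(nrow(obs)), key), function(i) {
    data.frame(plant_id = obs$plant_id[i[1]], date = date[i[1]],
               median_area = median(obs$area_px[i]),
               day_variance = if (length(i) > 1) var(obs$area_px[i]) else 0,
               mean_hue = mean(obs$hue_mean[i]),
               n_obs = length(i), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$plant_id, out$date), ]
  rownames(out) <- NULL
  out
}

#' Filter days with outlying within-day variance
#'
#' Removes summaries whose within-day area variance exceeds
#' `mean + 3 * sd` of the day variances computed over the whole summary
#' set (all plants). With identical variances (sd = 0) nothing is removed,
#' as the comparison is strict.
#'
#' @param summaries data.frame from [dailySummaries()] (possibly several
#'   plants).
#' @return the filtered data.frame, with the threshold in
#'   `attr(, "threshold")`.
#' @export
filterNoisyDays <- function(summaries) {
  stopifnot(nrow(summaries) >= 2)
  v <- summaries$day_variance
  threshold <- mean(v) + 3 * sd(v)
  out <- summaries[v <= threshold, , drop = FALSE]
  attr(out, "threshold") <- threshold
  out
}

#' Standardized area under the growth curve and AreaPerDay
#'
#' The growth curve (daily median areas) is standardized by subtracting the
#' first valid day's median (plants start from cuttings of varying size),
#' integrated by the trapezoidal rule over the first `windowDays` days with
#' gaps linearly interpolated, and divided by the window length:
#' `AreaPerDay = AUC_std / windowDays`. Days beyond the window are ignored;
#' if the curve ends before the window does, the integral runs to the last
#' observed day.
#'
#' @param curve data.frame for one plant with columns `date` (Date) or
#'   `day` (numeric day offsets) and `median_area`.
#' @param windowDays window length in days (default 30).
#' @return list: initialArea, aucStd (pixel-days), areaPerDay (pixels),
#'   windowDays, nDaysUsed.
#' @export
areaPerDay <- function(curve, windowDays = 30) {
  t <- if ("day" %in% names(curve)) as.numeric(curve$day)
       else as.numeric(curve$date - min(curve$date))
  ord <- order(t)
  t <- t[ord] - min(t)
  y <- curve$median_area[ord]
  keep <- t <= windowDays
  if (sum(keep) < 2)
    pgError("pgWindowTooShort", "fewer than 2 valid days inside the window")
  initial <- y[1]
  tEnd <- min(max(t), windowDays)
  knots <- sort(unique(c(t[t <= tEnd], tEnd)))
  yk <- stats::approx(t, y - initial, xout = knots, rule = 2)$y
  auc <- sum(diff(knots) * (head(yk, -1) + tail(yk, -1)) / 2)
  list(initialArea = initial, aucStd = auc, areaPerDay = auc / windowDays,
       windowDays = windowDays, nDaysUsed = sum(keep))
}

#' Rolling mean of a daily series
#'
#' Centered window, truncated at the series edges (edge days average over
#' the available neighbors), so the smoothed series has the same length as
#' the input.
#'
#' @param x numeric daily series.
#' @param window window width in days (odd; default 3).
#' @return numeric vector, same length as `x`.
#' @examples
#' rollingMeanHue(c(10, 20, 30, 40))   # 15 20 30 35
#' @export
rollingMeanHue <- function(x, window = 3) {
  n <- length(x)
  half <- (window - 1) %/% 2
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - half):min(n, i + half)]), numeric(1))
}

#' RateOfHue: early-window slope of the smoothed hue series
#'
#' Fits an ordinary least-squares regression of the smoothed daily mean hue
#' on the day index over the window
#' `[inoculationDay + fitStartOffset, inoculationDay + fitStartOffset + fitLength]`
#' (by default days 3 to 23 after inoculation: the first 20 days, starting
#' from day 3 because of the 3-day rolling mean). The slope is RateOfHue
#' (degrees/day, positive when symbiotic nitrogen fixation greens the
#' plant) and StartHue is the smoothed hue at the first fitted day.
#'
#' @param smoothed smoothed hue series (from [rollingMeanHue()]).
#' @param days day indices aligned with `smoothed` (default 0, 1, ...).
#' @param inoculationDay day index of inoculation (default 0).
#' @param fitStartOffset days skipped after inoculation (default 3).
#' @param fitLength fit window length in days (default 20).
#' @return list: rateOfHue, startHue, nDays, missing (TRUE with NA values
#'   when fewer than 3 days fall inside the window).
#' @export
rateOfHue <- function(smoothed, days = seq_along(smoothed) - 1,
                      inoculationDay = 0, fitStartOffset = 3, fitLength = 20) {
  lo <- inoculationDay + fitStartOffset
  hi <- lo + fitLength
  sel <- days >= lo & days <= hi & !is.na(smoothed)
  if (sum(sel) < 3)
    return(list(rateOfHue = NA_real_, startHue = NA_real_,
                nDays = sum(sel), missing = TRUE))
  d <- days[sel]; h <- smoothed[sel]
  fit <- lm(h ~ d)
  list(rateOfHue = unname(coef(fit)[2]), startHue = h[which.min(d)],
       nDays = sum(sel), missing = FALSE)
}

#' Per-plant trait table from an observation stream
#'
#' Runs the full trait pipeline: daily summaries, global variance
#' filtering, AreaPerDay over the window, 3-day hue smoothing and
#' RateOfHue/StartHue.
#'
#' @param obs observation data.frame (see [dailySummaries()]).
#' @param windowDays AUC window (default 30).
#' @param inoculationDay,fitStartOffset,fitLength see [rateOfHue()].
#' @param file optional CSV output path.
#' @return data.frame, one row per plant: barcode, initial_area,
#'   area_per_day, start_hue, rate_of_hue, n_days_used.
#' @export
traitTable <- function(obs, windowDays = 30, inoculationDay = 0,
                       fitStartOffset = 3, fitLength = 20, file = NULL) {
  summ <- filterNoisyDays(dailySummaries(obs))
  out <- do.call(rbind, lapply(split(summ, summ$plant_id), function(s) {
    s <- s[order(s$date), ]
    day <- as.numeric(s$date - min(s$date))
    gt <- areaPerDay(data.frame(day = day, median_area = s$median_area),
                     windowDays)
    rh <- rateOfHue(rollingMeanHue(s$mean_hue), days = day,
                    inoculationDay = inoculationDay,
                    fitStartOffset = fitStartOffset, fitLength = fitLength)
    data.frame(barcode = s$plant_id[1], initial_area = gt$initialArea,
               area_per_day = gt$areaPerDay, start_hue = rh$startHue,
               rate_of_hue = rh$rateOfHue, n_days_used = gt$nDaysUsed,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}

#' Wide time-series table
#'
#' Formats daily medians with each individual sample in a column and the
#' recorded time points (dates) in rows.
#'
#' @param summaries data.frame from [dailySummaries()].
#' @param value column to spread (default "median_area").
#' @param file optional CSV output path.
#' @return data.frame with a `date` column plus one column per plant.
#' @export
timeSeriesWide <- function(summaries, value = "median_area", file = NULL) {
  dates <- sort(unique(summaries$date))
  plants <- sort(unique(summaries$plant_id))
  out <- data.frame(date = dates)
  for (p in plants) {
    s <- summaries[summaries$plant_id == p, ]
    out[[p]] <- s[[value]][match(dates, s$date)]
  }
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}

#' Broad-sense heritability from variance components
#'
#' `h2_x = var_x / (var_clover + var_rhizobium + var_residual)` for the
#' clover and rhizobium components; their sum is the total fraction of
#' phenotypic variance attributable to the two genotypes.
#'
#' @param varClover,varRhizobium,varResidual nonnegative variance
#'   components, not all zero.
#' @return a [HeritabilityResult-class].
#' @examples
#' h2FromVarComps(2, 1, 7)   # 0.2, 0.1, 0.3
#' @export
h2FromVarComps <- function(varClover, varRhizobium, varResidual) {
  if (any(c(varClover, varRhizobium, varResidual) < 0))
    stop("variance components must be nonnegative")
  total <- varClover + varRhizobium + varResidual
  if (total == 0) stop("all variance components are zero")
  new("HeritabilityResult",
      varClover = varClover, varRhizobium = varRhizobium,
      varResidual = varResidual,
      h2Clover = varClover / total, h2Rhizobium = varRhizobium / total,
      h2Sum = (varClover + varRhizobium) / total)
}

#' Fit a trait's heritability via a linear mixed model
#'
#' Prepares the trait table (dropping uninoculated "NO" controls, plants
#' inoculated with contaminated strains, and explicitly excluded plants)
#' and delegates the two-random-effect fit to [lme4::lmer()]:
#' `trait ~ NS + EW + Round + Replicate + (1|Clover) + (1|Rhizobium)`,
#' with StartHue as an additional fixed covariate for RateOfHue (the rate
#' depends strongly on the starting conditions). The variance components
#' are then converted with [h2FromVarComps()].
#'
#' @param data data.frame with columns Clover, Rhizobium, NS, EW, Round,
#'   Replicate, the trait column, and StartHue when needed.
#' @param trait trait column name, "AreaPerDay" or "RateOfHue" (any numeric
#'   column is accepted).
#' @param includeStartHue add StartHue as fixed covariate (default TRUE
#'   when `trait == "RateOfHue"`).
#' @param contaminatedStrains rhizobium strain names to drop.
#' @param excludePlants barcodes to drop (e.g. abnormal growth patterns).
#' @return a [HeritabilityResult-class]; the fitted model is attached as
#'   `attr(, "model")` and the rows used as `attr(, "nUsed")`.
#' @export
fitHeritability <- function(data, trait = "AreaPerDay",
                            includeStartHue = identical(trait, "RateOfHue"),
                            contaminatedStrains = character(),
                            excludePlants = character()) {
  keep <- !(data$Rhizobium %in% c("NO", contaminatedStrains))
  if (length(excludePlants) && "barcode" %in% names(data))
    keep <- keep & !(data$barcode %in% excludePlants)
  keep <- keep & !is.na(data[[trait]])
  df <- data[keep, , drop = FALSE]
  fixed <- "NS + EW + Round + Replicate"
  if (includeStartHue) fixed <- paste(fixed, "+ StartHue")
  form <- stats::as.formula(sprintf(
    "%s ~ %s + (1|Clover) + (1|Rhizobium)", trait, fixed))
  fit <- lme4::lmer(form, data = df)
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) vc$vcov[vc$grp == g]
  res <- h2FromVarComps(getv("Clover"), getv("Rhizobium"), getv("Residual"))
  attr(res, "model") <- fit
  attr(res, "nUsed") <- nrow(df)
  res
}

#' @describeIn HeritabilityResult-class compact display
#' @param object a HeritabilityResult
#' @export
setMethod("show", "HeritabilityResult", function(object) {
  cat(sprintf(paste0("Broad-sense heritability: clover %.2f%%, ",
                     "rhizobium %.2f%%, sum %.2f%%\n"),
              100 * object@h2Clover, 100 * object@h2Rhizobium,
              100 * object@h2Sum))
})
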