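# Trait extraction: daily summaries, variance filtering, AreaPerDay,
# hue statistics, smoothing, RateOfHue, heritability.

obsRow <- function(plant, day, hour, area, hue = 80) {
  data.frame(plant_id = plant,
             timestamp = as.POSIXct(sprintf("2019-03-%02d %02d:00:00", day, hour),
                                    tz = "UTC"),
             area_px = area, hue_mean = hue, stringsAsFactors = FALSE)
}

test_that("daily summaries use the median and sample variance", {
  obs <- rbind(obsRow("p", 1, 10, 5), obsRow("p", 1, 11, 7),
               obsRow("p", 1, 12, 100),
               obsRow("p", 2, 10, 42),
               obsRow("p", 3, 10, 10), obsRow("p", 3, 11, 20))
  s <- dailySummaries(obs)
  expect_equal(s$median_area, c(7, 42, 15))   # median beats the outlier
  expect_equal(s$day_variance, c(var(c(5, 7, 100)), 0, 50))
  expect_equal(s$n_obs, c(3L, 1L, 2L))
})

test_that("the variance filter removes only extreme days", {
  base <- do.call(rbind, lapply(1:30, function(d)
    data.frame(plant_id = "p", date = as.Date("2019-03-01") + d,
               median_area = 100 + d, day_variance = 50 + (d %% 5),
               mean_hue = 80, n_obs = 10)))
  spike <- base[1, ]; spike$date <- as.Date("2019-04-15")
  spike$day_variance <- 1e6
  filtered <- filterNoisyDays(rbind(base, spike))
  expect_equal(nrow(filtered), 30)
  expect_false(as.Date("2019-04-15") %in% filtered$date)
  # all variances equal: sd = 0, strict comparison keeps everything
  same <- base; same$day_variance <- 50
  expect_equal(nrow(filterNoisyDays(same)), 30)
  # normally distributed variances: mean + 3 sd removes almost nothing
  set.seed(1)
  rnd <- base[rep(1:30, length.out = 100), ]
  rnd$date <- as.Date("2019-01-01") + 1:100
  rnd$day_variance <- rnorm(100, 2500, 500)
  expect_gte(nrow(filterNoisyDays(rnd)), 98)
})

test_that("AreaPerDay integrates the standardized curve", {
  lin <- data.frame(day = 0:30, median_area = 100 * (0:30))
  g <- areaPerDay(lin, windowDays = 30)
  expect_equal(g$aucStd, 45000)        # triangle: 0.5 * 30 * 3000
  expect_equal(g$areaPerDay, 1500)
  expect_equal(g$initialArea, 0)
  # constant curve integrates to zero
  expect_equal(areaPerDay(data.frame(day = 0:30, median_area = 500),
                          30)$areaPerDay, 0)
  # a gap at day 15 is linearly interpolated: identical result
  gap <- lin[lin$day != 15, ]
  expect_equal(areaPerDay(gap, 30)$areaPerDay, 1500)
  # invariant to adding a constant (standardization removes initial size)
  shifted <- lin; shifted$median_area <- shifted$median_area + 777
  expect_equal(areaPerDay(shifted, 30)$areaPerDay, 1500)
  # days beyond the window are ignored
  long <- data.frame(day = 0:40, median_area = 100 * (0:40))
  expect_equal(areaPerDay(long, 30)$areaPerDay, 1500)
  expect_error(areaPerDay(data.frame(day = 0, median_area = 1), 30),
               class = "pgWindowTooShort")
})

test_that("hue statistics weight bin centers by counts", {
  h <- hueHistogram(rep(120.2, 50))
  s <- hueStats(h)
  expect_equal(s$mean, 120.5)   # bin center of [120, 121)
  expect_equal(s$variance, 0)
  two <- setNames(c(25, 25), c(60, 100))   # half at 60, half at 100 degrees
  s2 <- hueStats(two)
  expect_equal(s2$mean, 80)
  expect_equal(s2$variance, 400)
  binned <- hueStats(hueHistogram(c(rep(59.7, 25), rep(99.7, 25))))
  expect_equal(binned$mean, 79.5)   # bin centers 59.5 and 99.5
  unif <- setNames(rep(10, 21), 50:70)
  expect_equal(hueStats(unif)$mean, 60)
  expect_true(hueStats(hueHistogram(numeric()))$missing)
  # total count equals the pixel count (area invariant)
  expect_equal(sum(hueHistogram(runif(321, 30, 150))), 321)
})

test_that("the rolling mean truncates at the edges", {
  expect_equal(rollingMeanHue(c(10, 20, 30, 40)), c(15, 20, 30, 35))
  expect_equal(rollingMeanHue(rep(5, 7)), rep(5, 7))
  expect_equal(rollingMeanHue(42), 42)
})

test_that("RateOfHue recovers slopes and shifts with the series", {
  days <- 0:29
  lin <- 60 + 2 * days
  r <- rateOfHue(rollingMeanHue(lin), days)
  expect_equal(r$rateOfHue, 2, tolerance = 1e-10)
  expect_equal(r$startHue, 60 + 2 * 3)   # smoothed value at day 3
  expect_equal(rateOfHue(rep(80, 30), days)$rateOfHue, 0)
  # constant shift moves startHue, not the rate
  r2 <- rateOfHue(rollingMeanHue(lin + 11), days)
  expect_equal(r2$rateOfHue, r$rateOfHue)
  expect_equal(r2$startHue, r$startHue + 11)
  # too few days inside the window is flagged missing
  expect_true(rateOfHue(c(1, 2), days = 0:1)$missing)
  # OLS is unbiased at the stated noise level
  set.seed(11)
  slopes <- replicate(200, {
    y <- 60 + 1.5 * days + rnorm(30, 0, 0.5)
    rateOfHue(rollingMeanHue(y), days)$rateOfHue
  })
  expect_lt(abs(mean(slopes) - 1.5), 0.1)
})

test_that("heritability fractions follow the variance-component formula", {
  h <- h2FromVarComps(2, 1, 7)
  expect_equal(h@h2Clover, 0.2)
  expect_equal(h@h2Rhizobium, 0.1)
  expect_equal(h@h2Sum, 0.3)
  h0 <- h2FromVarComps(0, 0, 5)
  expect_equal(h0@h2Sum, 0)
  expect_error(h2FromVarComps(0, 0, 0), "zero")
  expect_error(h2FromVarComps(-1, 0, 1), "nonnegative")
})

test_that("a delegated mixed-model fit recovers simulated heritability", {
  # variance ratios 0.33 / 0.04 / 0.63 at the experiment's genotype counts
  df <- simulateH2Data(nClover = 148, nRhizobium = 170, obsPerClover = 18,
                       varClover = 0.33, varRhizobium = 0.04,
                       varResidual = 0.63, seed = 42)
  res <- fitHeritability(df, "AreaPerDay")
  expect_equal(res@h2Clover, 0.33, tolerance = 0.05 / 0.33)
  expect_lt(abs(res@h2Rhizobium - 0.04), 0.04)
  # "NO" controls are dropped before fitting
  df2 <- rbind(df, within(df[1:50, ], {
    Rhizobium <- "NO"; AreaPerDay <- AreaPerDay + 100
  }))
  res2 <- fitHeritability(df2, "AreaPerDay")
  expect_equal(attr(res2, "nUsed"), nrow(df))
})

test_that("start hue and rate are negatively correlated under a shared asymptote", {
  # plants approach a common green asymptote: those starting yellower
  # (lower hue) have farther to go, hence steeper early slopes
  set.seed(3)
  days <- 0:29
  traits <- t(replicate(120, {
    start <- runif(1, 50, 90)
    hue <- 110 - (110 - start) * exp(-days / 12) + rnorm(30, 0, 1)
    r <- rateOfHue(rollingMeanHue(hue), days)
    c(r$startHue, r$rateOfHue)
  }))
  expect_lt(cor(traits[, 1], traits[, 2]), 0)
})

test_that("the trait table runs the full pipeline per plant", {
  obs <- do.call(rbind, lapply(0:27, function(d) rbind(
    obsRow("A", 1 + d, 10, 100 + 20 * d, hue = 60 + 1.5 * d),
    obsRow("A", 1 + d, 14, 104 + 20 * d, hue = 60 + 1.5 * d),
    obsRow("B", 1 + d, 10, 200, hue = 90))))
  tt <- traitTable(obs, windowDays = 27)
  expect_equal(sort(tt$barcode), c("A", "B"))
  expect_gt(tt$area_per_day[tt$barcode == "A"], 0)
  expect_equal(tt$area_per_day[tt$barcode == "B"], 0)
  expect_equal(tt$rate_of_hue[tt$barcode == "A"], 1.5, tolerance = 1e-6)
  expect_equal(tt$rate_of_hue[tt$barcode == "B"], 0)
  wide <- timeSeriesWide(dailySummaries(obs))
  expect_equal(dim(wide), c(28, 3))
  expect_equal(names(wide), c("date", "A", "B"))
})
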