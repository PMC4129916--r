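two_hourly <- function(days, f, start = "2012-02-01 00:00") {
  tm <- utc(start) + seq(0, days * 24 - 2, by = 2) * 3600
  h <- as.numeric(difftime(tm, utc(start), units = "hours"))
  cyto_ts(tm, f(h), "y")
}

test_that("span differencing removes a pure trend", {
  ts <- two_hourly(10, function(h) 50 + 0.3 * h)
  dc <- diel_component(ts, span_trend = 0.4, span_diel = 0.1)
  expect_lt(max(abs(dc$residual)), 0.01 * diff(range(ts$value)))
  # additivity is exact by construction
  expect_equal(dc$fit_diel, dc$trend + dc$residual, tolerance = 1e-12)
  expect_error(diel_component(ts, span_trend = 0.1, span_diel = 0.4),
               "span_diel")
})

test_that("a 24-h oscillation survives differencing with the right period", {
  ts <- two_hourly(12, function(h) 100 + 0.5 * h + 10 * sin(2 * pi * h / 24))
  dc <- diel_component(ts, span_trend = 0.4, span_diel = 0.05)
  src <- dc[dc$is_source, ]
  h <- as.numeric(difftime(src$time, ts$time[1], units = "hours"))
  expect_gt(stats::cor(src$residual, sin(2 * pi * h / 24)), 0.95)
  # dominant period by periodogram on the hourly residual
  sp <- stats::spec.pgram(dc$residual, plot = FALSE, detrend = TRUE)
  period <- 1 / sp$freq[which.max(sp$spec)]
  expect_lte(abs(period - 24), 1)
})

test_that("hourly profiles reproduce a noiseless sinusoid at sampled hours", {
  # sampling every 2 h for 8 days, UTC hours even; local hours odd (UTC+1)
  ts <- two_hourly(8, function(h) sin(2 * pi * (h %% 24) / 24))
  df <- data.frame(time = ts$time, value = ts$value)
  prof <- hourly_profile(df, use = "raw", tz_offset_h = 1)
  expect_equal(sum(prof$populated), 12)
  expect_true(all(prof$hour[prof$populated] %% 2 == 1))
  pop <- prof[prof$populated, ]
  utc_h <- (pop$hour - 1) %% 24
  expect_equal(pop$median, sin(2 * pi * utc_h / 24), tolerance = 1e-9)
  expect_equal(pop$n, rep(8, 12))
  expect_error(hourly_profile(df, window = c(ts$time[1], ts$time[1] + 86400)),
               "2 full days")
})

test_that("profile statistics match a brute-force group-by", {
  set.seed(31)
  tm <- utc("2012-02-01") + seq(0, 9 * 24 - 1) * 3600
  v <- rnorm(length(tm))
  df <- data.frame(time = tm, value = v)
  prof <- hourly_profile(df, use = "raw", tz_offset_h = 1)
  hr <- floor(local_hour(tm, 1))
  for (h in c(0, 7, 23)) {
    expect_equal(prof$median[prof$hour == h],
                 stats::median(v[hr == h]))
    expect_equal(prof$q1[prof$hour == h],
                 unname(stats::quantile(v[hr == h], 0.25)))
    expect_equal(prof$n[prof$hour == h], sum(hr == h))
  }
})

test_that("increase interval follows the configured rising arc", {
  # medians rising 19:00 -> 02:00 and falling otherwise (the picoeukaryote
  # first-pulse pattern), on all 24 bins
  pos <- (0:23 - 19) %% 24            # circular distance from 19:00
  med <- ifelse(pos <= 7, pos, 7 - (pos - 7) * 7 / 17)
  prof <- structure(data.frame(hour = 0:23, median = med, q1 = med, q3 = med,
                               n = 5L, populated = TRUE),
                    class = c("cyto_dielprofile", "data.frame"))
  iv <- increase_interval(prof)
  expect_equal(unname(iv), c(19L, 2L), ignore_attr = TRUE)
  expect_equal(division_hour_estimate(prof), 22.5)
})

test_that("degenerate monotone profiles are flagged", {
  prof <- structure(data.frame(hour = 0:23, median = 0:23 / 10, q1 = 0, q3 = 1,
                               n = 3L, populated = TRUE),
                    class = c("cyto_dielprofile", "data.frame"))
  iv <- increase_interval(prof)
  expect_true(isTRUE(attr(iv, "degenerate")))
  expect_equal(unname(iv), c(0L, 0L), ignore_attr = TRUE)
  flat <- prof; flat$median <- rep(1, 24)
  expect_equal(unname(peak_hour(flat)), 0L, ignore_attr = TRUE)
  expect_true(isTRUE(attr(peak_hour(flat), "tie")))
  expect_true(is.na(division_hour_estimate(flat)))
})

test_that("peak hour picks the unique maximum", {
  med <- -abs(0:23 - 18) / 10
  prof <- structure(data.frame(hour = 0:23, median = med, q1 = med, q3 = med,
                               n = 4L, populated = TRUE),
                    class = c("cyto_dielprofile", "data.frame"))
  expect_equal(peak_hour(prof), 18L, ignore_attr = TRUE)
  small <- prof[1:10, ]
  expect_error(peak_hour(structure(small, class = class(prof))), "12 populated")
})

test_that("synchronized division is recovered from the diel residual", {
  cfg <- quiet_scenario(days = 22, synchrony = 0.5, division_hour = 22)
  qp <- quiet_population(cfg)
  p <- qp$pop
  set.seed(41)
  idx <- seq(1, nrow(p), by = 2)
  tm <- p$time[idx]
  ab <- p$abundance[idx] * exp(rnorm(length(idx), 0, 0.05))
  fw <- p$mean_fws[idx] * exp(rnorm(length(idx), 0, 0.02))
  da <- diel_component(cyto_ts(tm, ab, "ab"), 0.3, 0.03)
  df <- diel_component(cyto_ts(tm, fw, "fws"), 0.3, 0.03)
  win <- c(min(tm) + 86400, max(tm) - 86400)
  pa <- hourly_profile(da, win)
  pf <- hourly_profile(df, win)
  est <- division_hour_estimate(pa)
  expect_lte(abs(circular_hour_diff(est, 22)), 2)
  # anti-phase: abundance maximum within 3 h of the FWS minimum
  popf <- pf[pf$populated, ]
  fws_min <- popf$hour[which.min(popf$median)]
  expect_lte(abs(circular_hour_diff(peak_hour(pa), fws_min)), 3)
  # FWS peaks before the division burst
  expect_lte(abs(circular_hour_diff(peak_hour(pf),
                                    22 - 6)), 3)
})
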