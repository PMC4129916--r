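hourly_series <- function(values, start = "2012-01-01 00:00") {
  data.frame(time = utc(start) + (seq_along(values) - 1) * 3600,
             value = values)
}

test_that("a V-shaped series yields one pulse with onset at the minimum", {
  h <- 0:400
  v <- 100 + 60 * abs(h - 150) / 150
  v[h <= 150] <- 100 + 60 * (150 - h[h <= 150]) / 150
  v[h > 150] <- 100 + 200 * (h[h > 150] - 150) / 250
  p <- detect_pulses(hourly_series(v))
  expect_equal(nrow(p), 1)
  expect_lte(abs(as.numeric(difftime(p$onset, utc("2012-01-01") + 150 * 3600,
                                     units = "hours"))), 1)
  expect_gte(p$fold_change, 1.5)
})

test_that("a monotone increasing series starts its pulse at the series start", {
  p <- detect_pulses(hourly_series(100 * exp((0:300) / 150)))
  expect_equal(nrow(p), 1)
  expect_equal(p$onset, utc("2012-01-01 00:00"))
  expect_equal(p$peak_time, utc("2012-01-01") + 300 * 3600)
})

test_that("small wiggles below the fold threshold are not pulses", {
  set.seed(5)
  v <- 100 + 5 * sin((0:500) / 20)
  p <- detect_pulses(hourly_series(v), min_fold = 1.5)
  expect_equal(nrow(p), 0)
  short <- hourly_series(c(1, 2, 3))
  expect_warning(p2 <- detect_pulses(short, persistence_h = 12), "persistence")
  expect_equal(nrow(p2), 0)
})

test_that("three staggered nutrient pulses are recovered with ordered onsets", {
  onsets <- utc(c("2012-02-05 00:00", "2012-02-27 00:00", "2012-03-20 00:00"))
  evs <- lapply(onsets, function(o)
    forcing_event("NO3NO2_uM", o, 2, "decaying_pulse", decay_h = 72))
  lags <- c(Picoeukaryotes = 1.5, Microphytoplankton = 1.0)
  cfg <- scenario_config(utc("2012-01-24"), utc("2012-04-06"),
    forcing_events = evs,
    cluster_params = lapply(names(lags), function(nm)
      cluster_params(nm, 5000, nutrient_gain = 0.5, response_lag_days = lags[[nm]],
                     loss_rate = 0.5 * 0.25, synchrony = 0)),
    noise_sd = zero_noise(), seed = 2)
  f <- simulate_forcing(cfg)
  pop <- simulate_population(f, cfg$cluster_params)
  pulse_tabs <- lapply(pop, function(p) {
    idx <- seq(1, nrow(p), by = 2)
    set.seed(9)
    obs <- p$abundance[idx] * exp(rnorm(length(idx), 0, 0.05))
    reg <- regularize(cyto_ts(p$time[idx], obs, "ab"), span = 0.03, degree = 2)
    detect_pulses(reg)
  })
  for (nm in names(pulse_tabs)) {
    p <- pulse_tabs[[nm]]
    expect_equal(nrow(p), 3)
    truth <- onsets + lags[[nm]] * 86400
    expect_true(all(abs(as.numeric(difftime(p$onset, truth, units = "hours"))) <= 12))
  }
  # succession: the shorter-lag cluster leads every pulse
  for (k in 1:3) {
    ord <- succession_order(pulse_tabs, k)
    expect_equal(unlist(ord)[1], "Microphytoplankton")
  }
})

test_that("succession order groups ties in the same hour", {
  mk <- function(onset) data.frame(onset = utc(onset), peak_time = utc(onset) + 86400,
                                   end_time = utc(onset) + 2 * 86400,
                                   peak_value = 1, fold_change = 2)
  tabs <- list(A = mk("2012-01-10 00:00"), B = mk("2012-01-10 12:00"),
               C = mk("2012-01-10 12:00"))
  ord <- succession_order(tabs, 1)
  expect_equal(ord[[1]], "A")
  expect_setequal(ord[[2]], c("B", "C"))
  expect_length(succession_order(tabs["A"], 1), 1)
})

test_that("an exactly shifted copy recovers its lag with r = 1", {
  tm <- utc("2012-01-01") + (0:699) * 3600
  base <- sin(2 * pi * (0:699) / 160) + (0:699) / 700
  env <- data.frame(time = tm, value = base)
  shift <- 72
  abun <- data.frame(time = tm,
                     value = c(rep(base[1], shift), base[1:(700 - shift)]))
  res <- windowed_ccf(env, abun, c(tm[150], tm[700]), lead_days = 0,
                      max_lag_days = 6)
  expect_equal(res$best_lag_days, 3.0)
  expect_equal(res$best_r, 1.0, tolerance = 1e-12)
  expect_true(res$significant)
  expect_true(all(abs(res$r[!is.na(res$r)]) <= 1))
  # self-correlation peaks at zero lag
  self <- windowed_ccf(env, env, c(tm[150], tm[700]), lead_days = 0,
                       max_lag_days = 6)
  expect_equal(self$best_lag_days, 0)
  expect_equal(self$best_r, 1)
})

test_that("an independent white-noise driver is rarely declared significant", {
  tm <- utc("2012-01-01") + (0:699) * 3600
  abun <- data.frame(time = tm, value = 1000 * exp(0.5 * sin(2 * pi * (0:699) / 350)))
  hits <- vapply(1:40, function(seed) {
    set.seed(seed)
    env <- data.frame(time = tm, value = rnorm(700))
    windowed_ccf(env, abun, c(tm[1], tm[700]), lead_days = 0,
                 max_lag_days = 10)$significant
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})

test_that("lags without enough overlap are dropped", {
  tm <- utc("2012-01-01") + (0:49) * 3600
  env <- data.frame(time = tm, value = rnorm(50))
  abun <- data.frame(time = tm, value = rnorm(50))
  res <- windowed_ccf(env, abun, c(tm[1], tm[50]), lead_days = 0, max_lag_days = 2)
  expect_true(any(is.na(res$r)))          # longest lags lack overlap
  expect_error(windowed_ccf(env, abun, c(tm[45], tm[50]), lead_days = 0,
                            max_lag_days = 10))
})
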