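random_fixture <- function(seed, n = NULL) {
  set.seed(seed)
  n <- if (is.null(n)) sample(100:700, 1) else n
  t0 <- utc("2012-01-01")
  tm <- t0 + sort(sample(0:(n * 8), n)) * 1800
  y <- 3 * sin(as.numeric(tm - t0) / 4e5) + rnorm(n, 0, 0.5)
  cyto_ts(tm, y, "y")
}

test_that("fits agree with the definitional weighted least-squares oracle", {
  for (seed in 1:8) {
    ts <- random_fixture(seed)
    span <- runif(1, 0.15, 0.6)
    degree <- sample(0:2, 1)
    fit <- loess_fit(ts, span, degree)
    probe <- round(seq(1, length(fit$grid_h), length.out = 15))
    ora <- vapply(fit$grid_h[probe], function(g)
      loess_oracle(fit$x_h, fit$y, g, span, degree), numeric(1))
    expect_lt(max(abs(fit$fitted[probe] - ora)), 1e-8)
  }
})

test_that("constants and polynomials are reproduced exactly", {
  tm <- utc("2012-01-01") + sort(sample(0:2000, 120)) * 3600
  h <- as.numeric(difftime(tm, tm[1], units = "hours"))
  f0 <- loess_fit(cyto_ts(tm, rep(7, 120), "c"), span = 0.4, degree = 2)
  expect_lt(max(abs(f0$fitted - 7)), 1e-9)
  expect_lt(max(abs(f0$slopes)), 1e-9)
  for (degree in 1:2) {
    y <- 1 + 2 * h + if (degree == 2) 0.05 * h^2 else 0
    fit <- loess_fit(cyto_ts(tm, y, "p"), span = 0.3, degree = degree)
    want <- 1 + 2 * fit$grid_h + if (degree == 2) 0.05 * fit$grid_h^2 else 0
    interior <- fit$grid_h > min(h) + 1 & fit$grid_h < max(h) - 1
    expect_lt(max(abs(fit$fitted[interior] - want[interior]) /
                  pmax(abs(want[interior]), 1)), 1e-9)
  }
  # exact line: slopes are constant at 2 per hour
  f1 <- loess_fit(cyto_ts(tm, 1 + 2 * h, "l"), span = 0.3, degree = 1)
  expect_lt(max(abs(f1$slopes - 2)), 1e-9)
})

test_that("regularize produces the hourly grid with SE and gap flags", {
  tm <- utc("2012-01-01") + seq(0, 198, by = 2) * 3600  # 100 2-hourly points
  y <- sin(2 * pi * seq_along(tm) / 30) + 5
  reg <- regularize(cyto_ts(tm, y, "y"), span = 0.2)
  expect_equal(nrow(reg), 199)                     # 2n - 1 hourly ticks
  expect_true(all(diff(as.numeric(reg$time)) == 3600))
  expect_true(all(reg$se >= 0))
  expect_false(any(reg$low_confidence))
  # knock out a 3-day hole: flagged, and SE rises inside it
  hole <- tm < utc("2012-01-04") | tm > utc("2012-01-07")
  reg2 <- regularize(cyto_ts(tm[hole], y[hole], "y"), span = 0.2, max_gap_h = 6)
  inside <- reg2$time > utc("2012-01-04 12:00") & reg2$time < utc("2012-01-06 12:00")
  expect_true(all(reg2$low_confidence[inside]))
  expect_gt(mean(reg2$se[inside]), 2 * mean(reg2$se[!reg2$low_confidence]))
  # the largest SE of the whole series occurs inside the hole
  expect_true(inside[which.max(reg2$se)])
})

test_that("prediction refuses extrapolation unless enabled", {
  ts <- random_fixture(3, n = 100)
  fit <- loess_fit(ts, 0.3, 2)
  beyond <- max(ts$time) + 3600
  expect_error(predict(fit, beyond), "outside the observed")
  p <- predict(fit, beyond, allow_extrapolation = TRUE)
  expect_true(is.finite(p$value))
  inside <- predict(fit, ts$time[50])
  expect_equal(inside$value,
               loess_oracle(fit$x_h, fit$y, fit$x_h[50], 0.3, 2),
               tolerance = 1e-8)
})

test_that("perturbing one point only moves fits whose neighbourhood holds it", {
  ts <- random_fixture(4, n = 150)
  fit1 <- loess_fit(ts, 0.2, 1)
  y2 <- ts$value
  k <- 75
  y2[k] <- y2[k] + 10
  fit2 <- loess_fit(cyto_ts(ts$time, y2, "y"), 0.2, 1)
  changed <- abs(fit2$fitted - fit1$fitted) > 1e-10
  q <- fit1$q
  dmax_j <- vapply(fit1$grid_h, function(g) sort(abs(fit1$x_h - g))[q], numeric(1))
  in_neigh <- abs(fit1$x_h[k] - fit1$grid_h) <= dmax_j + 1e-9
  # changed grid points must hold the perturbed time in their neighbourhood,
  # and points whose neighbourhood excludes it must be untouched
  expect_true(all(in_neigh[changed]))
  expect_true(all(!changed[!in_neigh]))
})

test_that("degenerate inputs error cleanly", {
  tm <- utc("2012-01-01") + (0:3) * 3600
  expect_error(loess_fit(cyto_ts(tm, 1:4, "y"), span = 0.01, degree = 2),
               "neighbourhood smaller")
  expect_error(loess_fit(cyto_ts(tm[1:2], 1:2, "y"), span = 1, degree = 2),
               "at least 4")
  ts <- cyto_ts(tm, c(1, NA, NA, NA), "y")
  expect_error(suppressMessages(loess_fit(ts, span = 1, degree = 0)),
               "at least 2")
})
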