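test_that("descriptors match hand-computed trapezoid values", {
  ev <- rbind(event_rows("e1", c(0, 2, 4, 2, 0)),
              event_rows("e2", 5))
  d <- compute_descriptors(raw_sample(ev))
  expect_equal(d$total_FLR, c(8, 5))     # trapezoid; length-1 degenerates to sum
  expect_equal(d$max_FLR, c(4, 5))
  expect_equal(d$len_FLR, c(5, 1))
  expect_equal(d$total_FWS, c(8, 5))
})

test_that("raised-cosine totals match the closed-form area A(L-1)/2", {
  set.seed(20)
  rows <- list()
  truth <- list()
  for (i in 1:50) {
    A <- runif(1, 1, 500); L <- sample(3:40, 1)
    rows[[i]] <- event_rows(sprintf("e%03d", i), raised_cosine(A, L))
    truth[[i]] <- data.frame(id = sprintf("e%03d", i), area = A * (L - 1) / 2,
                             A = A, L = L)
  }
  d <- compute_descriptors(raw_sample(data.table::rbindlist(rows)))
  tr <- do.call(rbind, truth)
  expect_equal(d$total_FWS, tr$area, tolerance = 1e-9)
  # pulse maximum equals the amplitude when the profile peaks on a sample
  odd <- tr$L %% 2 == 1
  expect_equal(d$max_FWS[odd], tr$A[odd], tolerance = 1e-12)
})

test_that("vectorized descriptors equal a brute-force per-event recomputation", {
  s <- synthesize_listmode(default_state(c("Picoeukaryotes", "HighFLO"),
                                         abundance = c(30, 20)),
                           all_cluster_params(), protocol2(noise_rate = 20),
                           utc("2012-02-01"), seed = 9)
  d <- compute_descriptors(s)
  ev <- as.data.frame(s$events)
  for (id in sample(d$event_id, 10)) {
    for (ch in cyto_channels()) {
      v <- ev$value_mV[ev$event_id == id & ev$channel == ch]
      brute_total <- if (length(v) == 1) v else sum(v) - (v[1] + v[length(v)]) / 2
      row <- d[d$event_id == id, ]
      expect_identical(row[[paste0("total_", ch)]], brute_total)
      expect_identical(row[[paste0("max_", ch)]], max(v))
      expect_identical(row[[paste0("len_", ch)]], length(v))
    }
  }
})

test_that("trigger filtering is boundary-inclusive and monotone in level", {
  ev <- rbind(event_rows("e1", flr = c(0, 6.9, 0), fws = c(0, 1, 0)),
              event_rows("e2", flr = c(0, 7.0, 0), fws = c(0, 1, 0)),
              event_rows("e3", flr = c(0, 12, 0), fws = c(0, 1, 0)))
  d <- compute_descriptors(raw_sample(ev))
  expect_equal(apply_trigger(d, "FLR", 7)$event_id, c("e2", "e3"))
  expect_equal(nrow(apply_trigger(d, "FLR", 0)), 3)     # level 0 = identity
  expect_error(apply_trigger(d, "XYZ", 1), "unknown trigger channel")
  s <- synthesize_listmode(default_state(abundance = 500), all_cluster_params(),
                           protocol1(noise_rate = 100), utc("2012-02-01"), seed = 10)
  dd <- compute_descriptors(s)
  levels <- c(0, 3, 7, 10, 20)
  counts <- vapply(levels, function(l) nrow(apply_trigger(dd, "FLR", l)), 0)
  expect_true(all(diff(counts) <= 0))
  retained7 <- apply_trigger(dd, "FLR", 7)$event_id
  retained10 <- apply_trigger(dd, "FLR", 10)$event_id
  expect_true(all(retained10 %in% retained7))
})

test_that("analysed volume follows flow x duration x efficiency", {
  expect_equal(analyzed_volume(list(flow_rate_mm3s = 9, duration_s = 600,
                                    volume_efficiency = 1)), 5.4)
  expect_equal(analyzed_volume(list(flow_rate_mm3s = 4.5, duration_s = 240,
                                    volume_efficiency = 0.35)), 0.378)
  expect_equal(analyzed_volume(list(flow_rate_mm3s = 1, duration_s = 1000)), 1)
  expect_equal(analyzed_volume(list(volume_cm3 = 4.9)), 4.9)  # measured overrides
  expect_error(analyzed_volume(list(flow_rate_mm3s = -1, duration_s = 10)),
               "positive")
})

test_that("abundance is count over volume", {
  expect_equal(abundance_from_count(1080, 5.4), 200)
  expect_equal(abundance_from_count(0, 5.4), 0)
  expect_error(abundance_from_count(-1, 5.4), "non-negative")
  expect_error(abundance_from_count(10, 0), "positive")
})

test_that("zero sideward scatter flags the ratio instead of infinity", {
  ev <- event_rows("e1", fws = c(0, 3, 0), sws = c(0, 0, 0))
  d <- compute_descriptors(raw_sample(ev))
  expect_false(d$ratio_defined)
  expect_true(is.na(d$ratio_FLO_SWS))
})
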