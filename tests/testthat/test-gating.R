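test_that("point-in-polygon is even-odd and boundary-inclusive", {
  vx <- c(0, 2, 2, 0); vy <- c(0, 0, 2, 2)
  expect_true(point_in_polygon(1, 1, vx, vy))
  expect_false(point_in_polygon(3, 1, vx, vy))
  expect_true(point_in_polygon(0, 1, vx, vy))    # edge
  expect_true(point_in_polygon(2, 2, vx, vy))    # vertex
  expect_false(point_in_polygon(2 + 1e-9, 1, vx, vy))
  # concave polygon: the notch is outside
  cx <- c(0, 4, 4, 2, 2, 0); cy <- c(0, 0, 3, 3, 1, 1)
  expect_true(point_in_polygon(1, 0.5, cx, cy))
  expect_false(point_in_polygon(1, 2, cx, cy))
  expect_true(point_in_polygon(3, 2, cx, cy))
})

test_that("self-intersecting gate polygons are rejected", {
  expect_error(gate("bow", "total_FWS", "total_FLR",
                    cbind(c(0, 2, 2, 0), c(0, 2, 0, 2))), "self-intersecting")
})

test_that("gate priority resolves overlapping gates", {
  scheme <- gating_scheme(list(
    gate("A", "total_FWS", "total_FLR", cbind(c(0, 2, 2, 0), c(0, 0, 2, 2)),
         x_scale = "linear", y_scale = "linear", priority = 2),
    gate("B", "total_FWS", "total_FLR", cbind(c(1, 3, 3, 1), c(1, 1, 3, 3)),
         x_scale = "linear", y_scale = "linear", priority = 1)))
  desc <- data.frame(total_FWS = c(0.5, 1.5, 2.5, 5), total_FLR = c(0.5, 1.5, 2.5, 5))
  expect_equal(as.character(assign_clusters(desc, scheme)),
               c("A", "B", "B", "Unassigned"))
})

test_that("an event in both the PicoFLO and picoeukaryote regions gates PicoFLO", {
  # small FWS, high FLO/SWS ratio, totals inside the picoeukaryote box
  ev <- event_rows("e1", fws = raised_cosine(12, 5), sws = raised_cosine(10, 5),
                   flo = raised_cosine(150, 5), fly = raised_cosine(5, 5),
                   flr = raised_cosine(25, 5))
  d <- compute_descriptors(raw_sample(ev))
  scheme <- default_gating_scheme()
  # confirm it sits inside the picoeukaryote totals box as well
  expect_true(log10(d$total_FWS) > 1.35 && log10(d$total_FWS) < 2.45)
  expect_true(log10(d$total_FLR) > 0.7 && log10(d$total_FLR) < 1.8)
  expect_equal(as.character(assign_clusters(d, scheme)), "PicoFLO")
})

test_that("non-positive values on log axes end up Unassigned, counted", {
  desc <- data.frame(max_FWS = c(10, 0), ratio_FLO_SWS = c(10, 5),
                     max_SWS = c(10, 10), max_FLR = c(10, 10),
                     total_FWS = c(-1, -1), total_FLR = c(1, 1),
                     total_FLO = c(1, 1))
  labels <- assign_clusters(desc, default_gating_scheme())
  expect_equal(as.character(labels), c("PicoFLO", "Unassigned"))
  expect_gte(attr(labels, "n_unscalable"), 1)
})

test_that("gating partitions every triggered event and matches truth labels", {
  st <- default_state(names(default_protocol_map()),
                      abundance = c(500, 400, 150, 20, 20, 30))
  s <- synthesize_listmode(st, all_cluster_params(), protocol2(noise_rate = 30),
                           utc("2012-02-01"), seed = 21)
  d <- compute_descriptors(s)
  d <- apply_trigger(d, "FLR", 10)
  labels <- assign_clusters(d, default_gating_scheme())
  # partition: every event gets exactly one label
  expect_length(labels, nrow(d))
  counts <- table(labels)
  expect_equal(sum(counts), nrow(d))
  # accuracy against truth (protocol 2: the four big clusters remain)
  m <- merge(data.frame(event_id = d$event_id, assigned = labels),
             as.data.frame(s$labels), by = "event_id")
  scored <- m[m$cluster %in% names(default_protocol_map()), ]
  expect_gt(mean(scored$assigned == scored$cluster), 0.99)
})

test_that("gating is consistent under a global amplitude rescaling", {
  st <- default_state(c("Picoeukaryotes", "Nanophytoplankton"), c(100, 60))
  s <- synthesize_listmode(st, all_cluster_params(), protocol2(),
                           utc("2012-02-01"), seed = 22)
  d <- compute_descriptors(s)
  scheme <- default_gating_scheme()
  base <- assign_clusters(d, scheme)
  k <- 10  # one decade up
  d2 <- d
  for (col in names(d2)) {
    if (grepl("^(total|max)_", col)) d2[[col]] <- d2[[col]] * k
  }
  d2$ratio_FLO_SWS <- d$ratio_FLO_SWS  # ratio is scale-free
  shifted <- scheme
  shifted$gates <- lapply(scheme$gates, function(g) {
    g$vertices[, 1] <- g$vertices[, 1] + if (g$x_axis != "ratio_FLO_SWS") log10(k) else 0
    g$vertices[, 2] <- g$vertices[, 2] + if (g$y_axis != "ratio_FLO_SWS") log10(k) else 0
    g
  })
  expect_identical(as.character(assign_clusters(d2, shifted)),
                   as.character(base))
})

test_that("gating schemes round-trip through YAML", {
  scheme <- default_gating_scheme()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_gating_scheme(scheme, path)
  r <- read_gating_scheme(path)
  expect_equal(length(r$gates), length(scheme$gates))
  for (i in seq_along(r$gates)) {
    expect_identical(r$gates[[i]]$name, scheme$gates[[i]]$name)
    expect_equal(r$gates[[i]]$vertices, scheme$gates[[i]]$vertices)
  }
})

test_that("cluster series route protocols and skip gap ticks", {
  sc <- quiet_scenario(days = 4, seed = 33)
  sc$gap_windows <- list(c(utc("2012-02-02 00:00"), utc("2012-02-03 00:00")))
  sc$instruments <- list(protocol1(), protocol2())
  # six clusters so the routing map applies
  sc$cluster_params <- all_cluster_params(scale = 0.05)
  dir <- withr::local_tempdir()
  run_campaign(sc, dir)
  series <- cluster_abundance_series(file.path(dir, "samples"),
                                     default_gating_scheme())
  expect_named(series, names(default_protocol_map()), ignore.order = TRUE)
  pe <- series$Picoeukaryotes
  gw <- sc$gap_windows[[1]]
  expect_false(any(pe$time >= gw[1] & pe$time <= gw[2]))
  # per-tick abundance equals count / volume (protocol 1 volume 0.378)
  expect_equal(pe$abundance, pe$count / pe$volume_cm3)
  expect_equal(unique(pe$volume_cm3), 0.378)
  expect_equal(unique(series$HighSWS$volume_cm3), 5.4)
})
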