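mk_fixes <- function(lon, lat, dt_min = 30, t0 = "2014-07-25 00:00:00") {
  data.frame(bird_id = "b1",
             t = as.POSIXct(t0, tz = "UTC") + seq_along(lon) * dt_min * 60,
             lon = lon, lat = lat)
}

test_that("speed classification uses a strict 10 km/h threshold", {
  # the threshold itself is travel; just below is forage_rest
  expect_equal(label_behaviour(10), "travel")
  expect_equal(label_behaviour(10 - 1e-12), "forage_rest")
  expect_true(is.na(label_behaviour(NA)))
  # ~10 km in 1 h through the full pipeline
  lat0 <- 70
  dlat <- 10 / haversine_km(0, lat0, 0, lat0 + 1)
  f <- mk_fixes(c(0, 0), c(lat0, lat0 + dlat), dt_min = 60)
  lf <- compute_speeds(f)
  expect_equal(lf$speed_kmh[2], 10, tolerance = 1e-6)
  # coincident fixes: zero speed, forage_rest
  f0 <- mk_fixes(c(0, 0), c(70, 70))
  lf0 <- compute_speeds(f0)
  expect_equal(lf0$speed_kmh[2], 0)
  expect_equal(lf0$behaviour[2], "forage_rest")
})

test_that("segment speed matches the haversine oracle", {
  f <- mk_fixes(c(-21.583, -21.0), c(70.733, 70.733), dt_min = 30)
  lf <- compute_speeds(f)
  # independent value: geosphere haversine gives 21.391 km over 0.5 h
  expect_equal(lf$speed_kmh[2], 21.391 / 0.5, tolerance = 1e-3)
})

test_that("degenerate fix input is reported", {
  f <- mk_fixes(c(0, 0.1), c(70, 70))
  f$t[2] <- f$t[1]
  expect_error(compute_speeds(f), "b1")
  expect_warning(compute_speeds(mk_fixes(0, 70)), "fewer than 2")
})

test_that("gap segments are excluded from behavioural labelling", {
  f <- mk_fixes(seq(0, 0.5, length.out = 6), rep(70, 6), dt_min = 15)
  f$t[4:6] <- f$t[4:6] + 3600 * 5 # 5-h hole before fix 4
  lf <- compute_speeds(f)
  expect_true(is.na(lf$behaviour[4]))
  expect_false(anyNA(lf$behaviour[c(2, 3, 5, 6)]))
})

test_that("behaviour labels partition the fixes (one unlabelled per track)", {
  cfg <- base_config(seed = 12, n_birds = 5)
  lf <- compute_speeds(gen_tracks(cfg))
  n_birds <- length(unique(lf$bird_id))
  expect_equal(sum(lf$behaviour == "forage_rest", na.rm = TRUE) +
               sum(lf$behaviour == "travel", na.rm = TRUE),
               nrow(lf) - n_birds)
})

test_that("trip segmentation recovers the embedded excursion", {
  cfg <- base_config(seed = 13, n_birds = 3)
  tr <- gen_tracks(cfg)
  truth <- attr(tr, "truth")
  trips <- segment_trips(compute_speeds(tr), cfg$colony)
  expect_equal(nrow(trips), 3)
  expect_true(all(trips$complete))
  m <- merge(trips, truth, by = "bird_id")
  expect_equal(m$max_distance_km, m$apex_km, tolerance = 1e-6)
  # triangle inequality: path length bounds the apex distance
  expect_true(all(trips$path_length_km >= trips$max_distance_km))
})

test_that("a track ending at sea yields an incomplete trip; a resident track none", {
  cfg <- base_config(seed = 14, n_birds = 1)
  tr <- gen_tracks(cfg)
  tr_cut <- tr[1:(nrow(tr) - 10), ] # remove the return to the colony
  trips <- segment_trips(compute_speeds(tr_cut), cfg$colony)
  expect_equal(nrow(trips), 1)
  expect_false(trips$complete[1])
  colony_only <- data.frame(
    bird_id = "b1",
    t = as.POSIXct("2014-07-25", tz = "UTC") + (1:10) * 900,
    lon = cfg$colony[1] + rnorm(10, 0, 1e-4),
    lat = cfg$colony[2] + rnorm(10, 0, 1e-4))
  expect_equal(nrow(segment_trips(colony_only, cfg$colony)), 0)
})

test_that("trip summaries and the between-group Wilcoxon behave as documented", {
  trips <- data.frame(
    bird_id = letters[1:6], trip = 1, complete = TRUE,
    start = Sys.time(), end = Sys.time() + 3600,
    duration_h = c(1, 2, 3, 4, 5, 6),
    path_length_km = c(1, 2, 3, 4, 5, 6),
    max_distance_km = c(1, 2, 3, 4, 5, 6), n_fixes = 10)
  # {1,2,3} vs {4,5,6}: W = 0 under the first-group convention,
  # exact two-sided p = 0.1 (2/20 of the possible assignments)
  res <- trip_summary(trips, rep(c("g1", "g2"), each = 3))
  w <- res$tests[res$tests$metric == "max_distance_km", ]
  expect_equal(w$W, 0)
  expect_equal(w$p, 0.1, tolerance = 1e-12)
  # identical groups: p = 1
  trips2 <- trips; trips2$max_distance_km <- rep(c(10, 20, 30), 2)
  trips2$duration_h <- trips2$path_length_km <- trips2$max_distance_km
  res2 <- trip_summary(trips2, rep(c("g1", "g2"), 3))
  expect_equal(res2$tests$p[1], 1)
  # group means / SDs
  s <- res$summary
  expect_equal(s$mean[s$group == "g1" & s$metric == "max_distance_km"], 2)
  expect_equal(s$sd[s$group == "g2" & s$metric == "duration_h"], 1)
})

test_that("distance to a polygon is zero inside and geodesic outside", {
  cfg <- base_config(seed = 1)
  ice <- gen_ice_polygon(cfg, edge_distance_km = 50, from = "colony")
  # a vertex of the polygon is at distance zero
  expect_equal(distance_to_polygon(ice[1, 1], ice[1, 2], ice), 0)
  # point 100 km due west of the (north-south) near edge
  p <- unproject_aeq(-50, 0, cfg$colony)
  d <- distance_to_polygon(p$lon, p$lat, ice, center = cfg$colony)
  expect_equal(d, 100, tolerance = 0.5)
  # inside point
  pin <- unproject_aeq(60, 0, cfg$colony)
  expect_equal(distance_to_polygon(pin$lon, pin$lat, ice,
                                   center = cfg$colony), 0)
  expect_error(distance_to_polygon(0, 70, cbind(0, 70)), "ring")
})

test_that("median ice distances recover the placed ice-edge positions", {
  cfg <- base_config(seed = 15, n_birds = 20)
  pts <- gen_tracks(cfg)
  lf <- compute_speeds(pts)
  fr <- lf[!is.na(lf$behaviour) & lf$behaviour == "forage_rest", ]
  for (d0 in c(23, 152)) {
    ice <- gen_ice_polygon(cfg, edge_distance_km = d0)
    med <- median(distance_to_polygon(fr$lon, fr$lat, ice,
                                      center = cfg$colony))
    # tolerance reflects the configured 26-km between-trip spread
    # (median SE ~ 26 * 1.25 / sqrt(20) ~ 7 km)
    expect_lt(abs(med - d0), 15)
  }
})
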