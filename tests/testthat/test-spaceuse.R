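test_that("the ad-hoc bandwidth follows the bivariate reference rule", {
  set.seed(21)
  x <- rnorm(64); y <- rnorm(64)
  x <- (x - mean(x)) / sd(x) # exactly unit variance
  y <- (y - mean(y)) / sd(y)
  expect_equal(adhoc_bandwidth(x, y), 64^(-1 / 6), tolerance = 1e-12)
})

test_that("the utilization distribution integrates to one and peaks at the data mode", {
  set.seed(22)
  x <- rnorm(1000); y <- rnorm(1000)
  ud <- kde_ud(x, y)
  expect_equal(sum(ud$z) * prod(ud$cell_km), 1, tolerance = 1e-6)
  peak <- which(ud$z == max(ud$z), arr.ind = TRUE)[1, ]
  expect_lt(sqrt(ud$x[peak[1]]^2 + ud$y[peak[2]]^2), 0.5)
  expect_error(kde_ud(rep(1, 10), rep(2, 10)), "bandwidth")
  expect_error(kde_ud(1:3, 1:3), "at least 5")
})

test_that("volume contours contain the stated mass, minimally", {
  set.seed(23)
  ud <- kde_ud(rnorm(500), rnorm(500))
  for (lev in c(0.5, 0.75, 0.95)) {
    vc <- volume_contour(ud, lev)
    cell_mass <- max(ud$z) * prod(ud$cell_km)
    expect_gte(vc$mass, lev)
    expect_lte(vc$mass, lev + cell_mass)
  }
  expect_error(volume_contour(ud, 1), "level")
  # level -> 1: area approaches the full grid extent
  a99 <- volume_contour(ud, 0.999)$area_km2
  full <- diff(range(ud$x)) * diff(range(ud$y))
  expect_gt(a99 / full, 0.3)
  expect_gt(a99, volume_contour(ud, 0.5)$area_km2)
})

test_that("75% contour area matches the bivariate-normal closed form", {
  set.seed(24)
  n <- 2000
  x <- rnorm(n); y <- rnorm(n)
  ud <- kde_ud(x, y, grid_n = 250)
  vc <- volume_contour(ud, 0.75)
  sigma2_eff <- (var(x) + var(y)) / 2 + ud$bandwidth^2
  analytic <- pi * 2 * log(1 / 0.25) * sigma2_eff # chi2_2 quantile x pi sigma^2
  expect_equal(vc$area_km2, analytic, tolerance = 0.07)
})

test_that("contained mass is insensitive to grid resolution", {
  set.seed(25)
  x <- rnorm(800); y <- rnorm(800)
  sq <- unit_square(-1, -1) * 1.5 # fixed polygon
  mass_in <- function(grid_n) {
    ud <- kde_ud(x, y, bandwidth = 0.3, grid_n = grid_n)
    pts <- expand.grid(x = ud$x, y = ud$y)
    inside <- point_in_polygon(pts$x, pts$y, sq)
    sum(ud$z[matrix(inside, length(ud$x))] * prod(ud$cell_km))
  }
  expect_lt(abs(mass_in(200) - mass_in(400)), 0.01)
})

test_that("overlap percentages cover the degenerate and analytic cases", {
  a <- unit_square()
  expect_equal(overlap(a, a)$pct_of_a, 100, tolerance = 1e-9)
  disj <- overlap(a, unit_square(5, 5))
  expect_equal(disj$area_intersection, 0)
  expect_equal(disj$pct_of_union, 0)
  # squares offset by 0.5 in x: intersection 0.5, union 1.5
  ov <- overlap(a, unit_square(0.5, 0), grid_n = 1000)
  expect_equal(ov$area_intersection, 0.5, tolerance = 0.01)
  expect_equal(ov$pct_of_a, 50, tolerance = 1)
  expect_equal(ov$pct_of_union, 100 / 3, tolerance = 1)
  # symmetry of the union denominator
  ba <- overlap(unit_square(0.5, 0), a, grid_n = 1000)
  expect_equal(ov$pct_of_union, ba$pct_of_union, tolerance = 0.5)
})

test_that("overlap agrees with a Monte-Carlo point-in-polygon oracle", {
  a <- unit_square()
  b <- unit_square(0.4, 0.3)
  ov <- overlap(a, b, grid_n = 800)
  set.seed(26)
  px <- runif(1e5, -0.1, 1.5); py <- runif(1e5, -0.1, 1.4)
  box <- 1.6 * 1.5
  in_a <- point_in_polygon(px, py, a)
  in_b <- point_in_polygon(px, py, b)
  expect_equal(ov$area_a, box * mean(in_a), tolerance = 0.01)
  expect_equal(ov$area_intersection, box * mean(in_a & in_b),
               tolerance = 0.02)
  expect_equal(ov$area_union, box * mean(in_a | in_b), tolerance = 0.01)
})

test_that("a tight forage cluster inside the band overlaps it almost fully", {
  set.seed(27)
  band <- band_polygon(cbind(80, seq(-200, 200, 20)),
                       cbind(130, seq(-200, 200, 20)))
  x <- rnorm(400, 105, 3); y <- rnorm(400, 0, 3)
  vc <- volume_contour(kde_ud(x, y), 0.75)
  expect_gt(overlap(vc, band)$pct_of_a, 95)
})

test_that("sighting histograms are binned and zoned correctly", {
  empty <- bin_sightings(numeric(0), numeric(0))
  expect_equal(nrow(empty), 0)
  one <- bin_sightings(-21.05, 7, bin_width = 0.1)
  expect_equal(sum(one$count > 0), 1)
  expect_equal(sum(one$count), 7)
  # uniform sightings give a flat histogram within multinomial noise
  set.seed(28)
  lon <- runif(2000, -22, -20)
  h <- bin_sightings(lon, rep(1, 2000), bin_width = 0.25)
  inner <- h$count[h$bin_mid > -22 & h$bin_mid < -20]
  expect_lt(max(abs(inner - mean(inner))) / mean(inner), 0.35)
  # zone labels relative to the isobath longitudes (ocean eastward)
  z <- bin_sightings(c(-21.9, -21.2, -20.2), c(1, 1, 1), bin_width = 0.1,
                     isobath_lons = c(-21.5, -20.8))
  got <- z$zone[z$count > 0]
  expect_equal(got, c("continental_shelf", "shelf_break", "open_ocean"))
})

test_that("a shelf-plus-break sighting scenario shows two abundance peaks", {
  set.seed(29)
  lon <- c(rnorm(600, -21.8, 0.08), rnorm(300, -21.0, 0.06))
  h <- bin_sightings(lon, rep(1, 900), bin_width = 0.1,
                     isobath_lons = c(-21.1, -20.5))
  # local maxima of the binned counts
  cnt <- h$count
  peaks <- which(diff(sign(diff(cnt))) == -2) + 1
  peak_pos <- h$bin_mid[peaks[order(cnt[peaks], decreasing = TRUE)][1:2]]
  expect_lt(min(abs(peak_pos - (-21.8))), 0.15)
  expect_lt(min(abs(peak_pos - (-21.0))), 0.15)
})
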