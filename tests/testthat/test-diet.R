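test_that("composition table: definitions of RA and OF", {
  one <- data.frame(sample_id = "s1", source = "at_sea", taxon = "A",
                    count = 5)
  tab <- composition_table(one, "source")
  expect_equal(tab$ra_mean, 100)
  expect_equal(tab$of, 100)
  # taxon present in 18 of 20 samples: OF 90%
  s <- do.call(rbind, lapply(1:20, function(i) data.frame(
    sample_id = sprintf("s%02d", i), source = "at_sea",
    taxon = c("A", "B"), count = c(if (i <= 18) 3 else 0, 7))))
  tab <- composition_table(s, "source")
  expect_equal(tab$of[tab$taxon == "A"], 90)
  # zero-total samples are dropped with a warning
  s0 <- rbind(s, data.frame(sample_id = "s21", source = "at_sea",
                            taxon = c("A", "B"), count = c(0, 0)))
  expect_warning(tab0 <- composition_table(s0, "source"), "zero total")
  expect_equal(tab0$n_samples[1], 20)
})

test_that("per-sample relative abundances sum to 100% before averaging", {
  cfg <- base_config(seed = 41)
  zs <- gen_zoo_samples(cfg, "continental_shelf", 8)
  tab <- composition_table(zs, "stratum")
  expect_equal(sum(tab$ra_mean), 100, tolerance = 1e-9)
})

test_that("Calanus groups dominate the published pouch compositions", {
  d <- diet_summary()
  cal <- d$taxon %in% c("C_hyperboreus", "C_glacialis", "C_finmarchicus")
  expect_equal(round(sum(d$gp2012_ra[cal])), 85)
  expect_equal(round(sum(d$gp2014_ra[cal])), 90)
})

test_that("selection index: point estimate, bootstrap moments and closed-form SD", {
  r <- lfsi(0.470, 0.176, 0.039, 0.027, seed = 1)
  expect_equal(r$point, 0.431)
  expect_equal(round(r$point, 2), 0.43)
  # gp = env: point 0, bootstrap mean near 0
  r0 <- lfsi(0.3, 0.05, 0.3, 0.05, seed = 2)
  expect_equal(r0$point, 0)
  expect_lt(abs(r0$boot_mean), 4 * r0$boot_sd / sqrt(r0$n_boot))
  # independent-normal difference: sd = sqrt(gp_sd^2 + env_sd^2)
  rsd <- lfsi(0.470, 0.176, 0.039, 0.027, n_boot = 1e5, seed = 3)
  closed <- sqrt(0.176^2 + 0.027^2)
  mc_se <- closed / sqrt(2 * 1e5)
  expect_lt(abs(rsd$boot_sd - closed), 3 * mc_se)
  expect_true(r$ci_low <= r$boot_mean && r$boot_mean <= r$ci_high)
  expect_error(lfsi(0.5, 0.1, 0.5, 0.1, n_boot = 10), "n_boot")
  expect_error(lfsi(1.5, 0.1, 0.5, 0.1), "gp_mean")
})

test_that("lfsi is reproducible under a seed and table indices sum to zero", {
  a <- lfsi(0.4, 0.1, 0.2, 0.05, seed = 9)
  b <- lfsi(0.4, 0.1, 0.2, 0.05, seed = 9)
  expect_identical(a, b)
  # full shared taxon universe: sum of point estimates is zero
  cfg <- base_config(seed = 42)
  gp <- composition_table(gen_gular_samples(cfg, 2014, 15), "year")
  env <- composition_table(gen_zoo_samples(cfg, "continental_shelf", 15),
                           "stratum")
  tab <- lfsi_table(gp, env, n_boot = 200, seed = 4)
  expect_equal(sum(tab$point), 0, tolerance = 1e-9)
  expect_true(all(tab$point >= -1 & tab$point <= 1))
})

test_that("net-haul densities follow the swept-cylinder formula", {
  expect_equal(density_per_m3(0), 0)
  # 100 individuals, WP2 geometry: 100 / (pi * 0.285^2 * 50)
  expect_equal(density_per_m3(100), 100 / (pi * 0.285^2 * 50))
  expect_equal(density_per_m3(100), 7.84, tolerance = 0.005)
  expect_equal(density_per_m3(100, haul_depth = 25),
               2 * density_per_m3(100, haul_depth = 50))
  expect_error(density_per_m3(10, haul_depth = 0), "positive")
})

test_that("summary t-tests reproduce the published between-year statistics", {
  d <- diet_summary()
  t_for <- function(taxon) {
    r <- d[d$taxon == taxon, ]
    two_sample_t_summary(r$gp2012_ra, r$gp2012_sd, 20,
                         r$gp2014_ra, r$gp2014_sd, 20)
  }
  hyp <- t_for("C_hyperboreus")
  expect_equal(hyp$df, 38)
  expect_equal(hyp$t, 2.43, tolerance = 0.01)
  expect_equal(t_for("C_glacialis")$t, -5.28, tolerance = 0.01)
  expect_equal(t_for("C_finmarchicus")$t, -2.75, tolerance = 0.01)
  ident <- two_sample_t_summary(5, 2, 10, 5, 2, 10)
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(two_sample_t_summary(5, 0, 10, 5, 0, 10), "undefined")
})

test_that("Calanus size classification follows the stage rules and tie convention", {
  rules <- calanus_rules()
  expect_equal(classify_calanus("CV", 2.0), "finmarchicus")
  expect_equal(classify_calanus("CV", 3.0), "glacialis")
  expect_equal(classify_calanus("CV", 4.0), "hyperboreus")
  # boundary goes to the larger species
  expect_equal(classify_calanus("CV", 2.45), "glacialis")
  expect_equal(classify_calanus("CV", 3.40), "hyperboreus")
  expect_warning(out <- classify_calanus("CII", 1.0), "no size rule")
  expect_true(is.na(out))
  # three-component mixture with cut-points at the density minima
  set.seed(43)
  n <- 500
  spp <- sample(c("finmarchicus", "glacialis", "hyperboreus"), n, TRUE)
  mu <- c(finmarchicus = 2.1, glacialis = 2.9, hyperboreus = 3.9)
  len <- rnorm(n, mu[spp], 0.15)
  got <- classify_calanus(rep("CV", n), len, rules)
  expect_gte(mean(got == spp), 0.95)
})

test_that("Bray-Curtis distances are a semimetric with the right extremes", {
  s <- data.frame(sample_id = rep(c("a", "b", "c"), each = 2),
                  taxon = rep(c("t1", "t2"), 3),
                  count = c(5, 5, 5, 5, 0, 10))
  bc <- bray_curtis_ward(s, k = 2)
  m <- as.matrix(bc$dist)
  expect_equal(m["a", "b"], 0)           # identical samples
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m, t(m))
  disj <- data.frame(sample_id = c("a", "b"), taxon = c("t1", "t2"),
                     count = c(5, 7))
  expect_equal(as.numeric(bray_curtis_ward(disj, k = 2)$dist), 1)
  # matches the direct formula on counts
  u <- c(5, 5); v <- c(0, 10)
  expect_equal(m["a", "c"], sum(abs(u - v)) / sum(u + v))
  expect_warning(bray_curtis_ward(rbind(s, data.frame(
    sample_id = "z", taxon = "t1", count = 0)), k = 2), "all-zero")
})

test_that("two simulated communities are recovered by the cluster cut", {
  cfg <- base_config(seed = 44)
  shelf <- gen_zoo_samples(cfg, "continental_shelf", 10)
  ocean <- gen_zoo_samples(cfg, "open_ocean", 10)
  bc <- bray_curtis_ward(rbind(shelf, ocean), k = 2)
  truth <- rep(1:2, each = 10)
  expect_gte(rand_index(unname(bc$groups), truth), 0.9)
})

test_that("habitat density comparison: degenerate, separated and rank-oracle cases", {
  # identical constants: H = 0, p = 1 by convention
  r0 <- habitat_density_compare(rep(4, 9), rep(c("a", "b", "c"), 3))
  expect_equal(r0$kw$H, 0)
  expect_equal(r0$kw$p, 1)
  expect_true(all(r0$letters == "a"))
  # direct rank computation oracle: H = 12/(N(N+1)) sum R^2/n - 3(N+1)
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  ranks <- rank(x)
  H_oracle <- 12 / (9 * 10) *
    sum(tapply(ranks, g, sum)^2 / 3) - 3 * 10
  r <- habitat_density_compare(x, g, alpha = 0.05)
  expect_equal(r$kw$H, H_oracle)
  expect_equal(r$kw$H, 7.2, tolerance = 1e-9)
  expect_equal(r$kw$p, 0.0273, tolerance = 1e-2)
  # strongly shifted strata get three distinct letters
  set.seed(45)
  y <- c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1), rnorm(10, 20, 0.1))
  gg <- rep(c("shelf", "brk", "ocean"), each = 10)
  rs <- habitat_density_compare(y, gg, alpha = 0.01)
  expect_equal(length(unique(rs$letters)), 3)
  expect_warning(habitat_density_compare(c(y, 1), c(gg, "single")),
                 "excluding strata")
})
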