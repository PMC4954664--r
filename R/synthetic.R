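# Synthetic inputs for the whole pipeline. Every generator runs on its own
# RNG sub-stream derived from config$seed, so adding or re-running one
# generator never perturbs the draws of another, and a fixed seed gives
# byte-identical output files.

.SEED_TRACKS <- 101L
.SEED_DIVES <- 202L
.SEED_ZOO <- 303L
.SEED_GULAR <- 404L
.SEED_GROWTH <- 505L
.SEED_SIC <- 606L

#' Published diet / zooplankton composition summary
#'
#' Per-taxon mean relative abundance (%), its SD and occurrence frequency
#' (%) of zooplankton in little auk gular pouches (2012, 2014) and in
#' at-sea net hauls (2014) over three bathymetric strata off East
#' Greenland. Shipped as a plain-text table; used both as the default
#' composition structure of the synthetic generators and as input for the
#' summary-level diet statistics (selection index, between-year t-tests).
#'
#' @return data.frame with one row per taxon group; attribute `group_n`
#'   holds the number of samples behind each column group.
#' @export
diet_summary <- function() {
  path <- system.file("extdata", "little_auk_diet_summary.csv",
                      package = "aukforage", mustWork = TRUE)
  d <- read.csv(path, stringsAsFactors = FALSE)
  attr(d, "group_n") <- c(gp2012 = 20, gp2014 = 20,
                          shelf = 11, break. = 5, ocean = 4)
  d
}

.default_profiles <- function() {
  d <- diet_summary()
  norm <- function(x) x / sum(x)
  list(
    community = list(
      continental_shelf = setNames(norm(d$shelf_ra), d$taxon),
      shelf_break = setNames(norm(d$break_ra), d$taxon),
      open_ocean = setNames(norm(d$ocean_ra), d$taxon)
    ),
    pouch = list(
      `2012` = list(mean = setNames(norm(d$gp2012_ra), d$taxon),
                    sd = setNames(d$gp2012_sd / 100, d$taxon)),
      `2014` = list(mean = setNames(norm(d$gp2014_ra), d$taxon),
                    sd = setNames(d$gp2014_sd / 100, d$taxon))
    )
  )
}

#' Scenario configuration for the synthetic-data generators
#'
#' Bundles and validates every tunable of the simulated study system: a
#' colony of central-place foragers commuting to a feeding ground near the
#' shelf break, diving in bouts through the day, delivering zooplankton
#' loads to linearly growing chicks.
#'
#' Defaults reflect the study system the package emulates: 15-min GPS
#' fixes, foraging grounds ~100 km from the colony (maximum trip distances
#' of roughly 89-108 km between years), ~270 dives per 24 h of ~17-21 m and
#' ~55-60 s, at-sea communities with the shelf / shelf-break / open-ocean
#' composition structure of [diet_summary()], and linear chick growth over
#' ages 4-14 d with a per-chick random intercept.
#'
#' @param seed integer master seed; each generator derives a sub-stream.
#' @param n_birds number of tracked birds.
#' @param fix_interval GPS sampling interval, minutes.
#' @param commute_speed mean commuting flight speed, km/h.
#' @param forage_speed_max upper bound of generated foraging/drifting
#'   speeds, km/h (below the 10 km/h classification threshold).
#' @param target_distance mean distance colony to feeding ground, km.
#' @param distance_sd between-trip SD of that distance, km.
#' @param forage_hours hours spent in the low-speed foraging/resting phase
#'   per trip (the within-trip time budget is a free parameter, not an
#'   estimate).
#' @param n_dives_per_day expected dives per 24 h.
#' @param dive_depth_mean,dive_depth_sd maximum dive depth, m.
#' @param dive_duration_mean,dive_duration_sd dive duration, s.
#' @param community_profiles named list stratum -> relative-abundance
#'   vector (sums to 1).
#' @param pouch_profiles named list year -> list(mean, sd) of
#'   relative-abundance vectors.
#' @param dirichlet_conc Dirichlet concentration for between-sample
#'   overdispersion of community composition.
#' @param growth_intercept,growth_slope chick growth line, g and g/day.
#' @param chick_sd SD of the per-chick random intercept, g.
#' @param resid_sd residual SD of mass, g.
#' @param ice_edge_distance distance from the feeding ground to the
#'   consolidated-ice edge, km.
#' @param colony c(lon, lat) of the colony, degrees.
#' @return validated list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_birds = 6L,
                            fix_interval = 15,
                            commute_speed = 45,
                            forage_speed_max = 8,
                            target_distance = 100,
                            distance_sd = 26,
                            forage_hours = 24,
                            n_dives_per_day = 270L,
                            dive_depth_mean = 19, dive_depth_sd = 4,
                            dive_duration_mean = 57, dive_duration_sd = 5,
                            community_profiles = NULL,
                            pouch_profiles = NULL,
                            dirichlet_conc = 50,
                            growth_intercept = 20, growth_slope = 6,
                            chick_sd = 5, resid_sd = 5,
                            ice_edge_distance = 150,
                            colony = c(-21.583, 70.733)) {
  prof <- .default_profiles()
  if (is.null(community_profiles)) community_profiles <- prof$community
  if (is.null(pouch_profiles)) pouch_profiles <- prof$pouch
  cfg <- list(
    seed = as.integer(seed), n_birds = as.integer(n_birds),
    fix_interval = fix_interval, commute_speed = commute_speed,
    forage_speed_max = forage_speed_max,
    target_distance = target_distance, distance_sd = distance_sd,
    forage_hours = forage_hours,
    n_dives_per_day = as.integer(n_dives_per_day),
    dive_depth_mean = dive_depth_mean, dive_depth_sd = dive_depth_sd,
    dive_duration_mean = dive_duration_mean,
    dive_duration_sd = dive_duration_sd,
    community_profiles = community_profiles,
    pouch_profiles = pouch_profiles, dirichlet_conc = dirichlet_conc,
    growth_intercept = growth_intercept, growth_slope = growth_slope,
    chick_sd = chick_sd, resid_sd = resid_sd,
    ice_edge_distance = ice_edge_distance, colony = colony
  )
  .validate_config(cfg)
  class(cfg) <- "scenario_config"
  cfg
}

.validate_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) stop("invalid config: ", msg,
                                                   call. = FALSE)
  stopifnot_msg(cfg$n_birds >= 1, "n_birds must be >= 1")
  stopifnot_msg(cfg$fix_interval > 0, "fix_interval must be > 0")
  stopifnot_msg(cfg$commute_speed > 0 && cfg$forage_speed_max > 0,
                "speeds must be positive")
  stopifnot_msg(cfg$n_dives_per_day >= 0, "n_dives_per_day must be >= 0")
  sds <- c(cfg$distance_sd, cfg$dive_depth_sd, cfg$dive_duration_sd,
           cfg$chick_sd, cfg$resid_sd)
  stopifnot_msg(all(sds >= 0), "all SDs must be >= 0")
  stopifnot_msg(cfg$dive_depth_mean >= 0 && cfg$dive_duration_mean > 0,
                "dive depth/duration parameters must be non-negative")
  for (p in cfg$community_profiles)
    stopifnot_msg(abs(sum(p) - 1) < 1e-9 && all(p >= 0),
                  "community profile must be a probability vector")
  for (p in cfg$pouch_profiles) {
    stopifnot_msg(abs(sum(p$mean) - 1) < 1e-9 && all(p$mean >= 0),
                  "pouch mean profile must be a probability vector")
    stopifnot_msg(all(p$sd >= 0), "pouch SDs must be >= 0")
  }
  invisible(cfg)
}

#' Simulate GPS tracks of central-place foraging trips
#'
#' Each bird performs `n_trips` out-and-back excursions: a directional
#' commuting leg (speeds well above 10 km/h) towards a feeding ground at
#' roughly `target_distance` km, a long low-speed foraging/resting phase
#' (speeds below `forage_speed_max`), and a directional return. Tracks are
#' built in a planar frame centred on the colony, then inverse-projected
#' to WGS84 lon/lat.
#'
#' @param config [scenario_config()].
#' @param n_trips trips per bird.
#' @return data.frame of fixes (`bird_id`, `t`, `lon`, `lat`) with
#'   attribute `truth`: one row per trip with the generated apex distance
#'   (km) and phase boundaries.
#' @export
gen_tracks <- function(config, n_trips = 1L) {
  .validate_config(config)
  withr::with_seed(config$seed + .SEED_TRACKS, {
    dt <- config$fix_interval / 60 # hours
    t0 <- as.POSIXct("2014-07-25 00:00:00", tz = "UTC")
    fixes <- list()
    truth <- list()
    for (b in seq_len(config$n_birds)) {
      bird <- sprintf("bird%02d", b)
      xy <- matrix(numeric(0), ncol = 2)
      for (trip in seq_len(n_trips)) {
        apex <- max(20, rnorm(1, config$target_distance, config$distance_sd))
        bearing <- rnorm(1, 0, 10) * pi / 180 # around due east
        ux <- cos(bearing); uy <- sin(bearing)
        # at colony before departure
        pre <- cbind(runif(2, -0.1, 0.1), runif(2, -0.1, 0.1))
        # outbound commute
        pos <- c(0, 0)
        out <- list()
        repeat {
          sp <- max(12, rnorm(1, config$commute_speed, 3))
          jit <- rnorm(2, 0, 0.3)
          pos <- pos + c(ux, uy) * sp * dt + jit
          r <- sqrt(sum(pos^2))
          if (r >= apex) { # land on the feeding ground, no overshoot
            pos <- pos * (apex / r)
            out[[length(out) + 1]] <- pos
            break
          }
          out[[length(out) + 1]] <- pos
        }
        out <- do.call(rbind, out)
        # foraging / resting cluster around the apex
        centre <- pos
        n_f <- max(4L, round(config$forage_hours / dt))
        fg <- matrix(NA_real_, n_f, 2)
        for (i in seq_len(n_f)) {
          sp <- runif(1, 0.1, 0.9 * config$forage_speed_max)
          ang <- runif(1, 0, 2 * pi)
          cand <- pos + c(cos(ang), sin(ang)) * sp * dt
          # soft pull keeps the cluster near the feeding ground
          cand <- cand + 0.05 * (centre - cand)
          step <- sqrt(sum((cand - pos)^2))
          if (step / dt >= config$forage_speed_max)
            cand <- pos + (cand - pos) * (0.9 * config$forage_speed_max * dt / step)
          pos <- cand
          fg[i, ] <- pos
        }
        # return commute
        ret <- list()
        repeat {
          sp <- max(12, rnorm(1, config$commute_speed, 3))
          to_col <- -pos
          d <- sqrt(sum(to_col^2))
          if (d <= sp * dt) { pos <- c(0, 0); ret[[length(ret) + 1]] <- pos; break }
          pos <- pos + to_col / d * sp * dt + rnorm(2, 0, 0.3)
          ret[[length(ret) + 1]] <- pos
        }
        ret <- do.call(rbind, ret)
        post <- cbind(runif(2, -0.1, 0.1), runif(2, -0.1, 0.1))
        seg <- rbind(pre, out, fg, ret, post)
        at_sea <- rbind(out, fg, ret)
        truth[[length(truth) + 1]] <- data.frame(
          bird_id = bird, trip = trip,
          apex_target_km = apex,
          apex_km = max(sqrt(rowSums(at_sea^2))), # realized max distance
          n_out = nrow(out), n_forage = n_f, n_return = nrow(ret)
        )
        xy <- rbind(xy, seg)
      }
      ll <- unproject_aeq(xy[, 1], xy[, 2], config$colony)
      fixes[[b]] <- data.frame(
        bird_id = bird,
        t = t0 + (b - 1) * 3600 + seq_len(nrow(xy)) * config$fix_interval * 60,
        lon = ll$lon, lat = ll$lat
      )
    }
    out <- do.call(rbind, fixes)
    rownames(out) <- NULL
    attr(out, "truth") <- do.call(rbind, truth)
    out
  })
}

#' Simulate a time-depth-recorder series with embedded ground truth
#'
#' Square-wave dives of known start, end and depth are placed without
#' overlap on a surface-noise baseline. The number of dives is Poisson
#' with mean `n_dives_per_day` scaled to the record length.
#'
#' @param config [scenario_config()].
#' @param hours record length.
#' @param interval_s sampling interval, one of 1, 2 or 4 s.
#' @param tag_model tag identifier attached to the series. For
#'   `"DST micro-TD"` the emitted raw depth is the tag-frame (uncalibrated)
#'   depth, i.e. [calibrate_depth()] recovers the true depth.
#' @return list with `series` (data.frame `time_s`, `raw_depth`,
#'   `tag_model`), `truth` (data.frame of embedded dives), `interval_s`.
#' @export
gen_dives <- function(config, hours = 24, interval_s = 4, tag_model = "G5") {
  .validate_config(config)
  if (!interval_s %in% c(1, 2, 4))
    stop("interval_s must be 1, 2 or 4 seconds")
  withr::with_seed(config$seed + .SEED_DIVES, {
    span <- hours * 3600
    time_s <- seq(0, span - interval_s, by = interval_s)
    depth <- abs(rnorm(length(time_s), 0, 0.05))
    n <- rpois(1, config$n_dives_per_day * hours / 24)
    truth <- data.frame(start_s = numeric(0), end_s = numeric(0),
                        max_depth = numeric(0), duration = numeric(0))
    if (n > 0) {
      dur <- pmax(3 * interval_s,
                  round(rnorm(n, config$dive_duration_mean,
                              config$dive_duration_sd) / interval_s) * interval_s)
      gap <- 2 * interval_s
      free <- span - sum(dur) - n * gap
      if (free < 0) stop("record too short for the requested dive load")
      starts <- sort(runif(n, 0, free))
      starts <- floor((starts + cumsum(c(0, dur[-n] + gap))) / interval_s) * interval_s
      dmax <- pmax(5, rnorm(n, config$dive_depth_mean, config$dive_depth_sd))
      for (i in seq_len(n)) {
        idx <- which(time_s >= starts[i] & time_s < starts[i] + dur[i])
        depth[idx] <- dmax[i] + rnorm(length(idx), 0, 0.2)
        depth[idx][which.max(depth[idx])] <- dmax[i]
      }
      truth <- data.frame(start_s = starts, end_s = starts + dur,
                          max_depth = dmax, duration = dur)
    }
    raw <- if (tag_model == "DST micro-TD")
      (depth - 0.4498) / 1.0473 else depth
    list(series = data.frame(time_s = time_s, raw_depth = raw,
                             tag_model = tag_model),
         truth = truth, interval_s = interval_s)
  })
}

.rdirichlet1 <- function(alpha) {
  g <- ifelse(alpha > 0, rgamma(length(alpha), shape = alpha, rate = 1), 0)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate at-sea zooplankton samples for one bathymetric stratum
#'
#' Counts are Dirichlet-multinomial around the stratum's composition
#' profile: per-sample relative abundances are Dirichlet with
#' concentration `dirichlet_conc`, counts multinomial with a Poisson
#' total.
#'
#' @param config [scenario_config()].
#' @param stratum one of `"continental_shelf"`, `"shelf_break"`,
#'   `"open_ocean"`.
#' @param n_samples number of hauls.
#' @param total_mean expected individuals per haul.
#' @return long data.frame: `sample_id`, `source`, `year`, `stratum`,
#'   `taxon`, `count`, `haul_depth`, `net_diameter`.
#' @export
gen_zoo_samples <- function(config, stratum, n_samples, total_mean = 400) {
  .validate_config(config)
  strata <- names(config$community_profiles)
  if (!stratum %in% strata)
    stop("unknown stratum '", stratum, "'; expected one of: ",
         paste(strata, collapse = ", "))
  prof <- config$community_profiles[[stratum]]
  withr::with_seed(config$seed + .SEED_ZOO + 10L * match(stratum, strata), {
    rows <- vector("list", n_samples)
    for (i in seq_len(n_samples)) {
      p <- .rdirichlet1(config$dirichlet_conc * prof)
      total <- rpois(1, total_mean) + 1
      cnt <- as.integer(rmultinom(1, total, p))
      rows[[i]] <- data.frame(
        sample_id = sprintf("%s_%02d", stratum, i),
        source = "at_sea", year = 2014, stratum = stratum,
        taxon = names(prof), count = cnt,
        haul_depth = 50, net_diameter = 0.57
      )
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(sample_id = character(0), source = character(0),
                        year = integer(0), stratum = character(0),
                        taxon = character(0), count = integer(0),
                        haul_depth = numeric(0), net_diameter = numeric(0))
    rownames(out) <- NULL
    out
  })
}

#' Simulate gular-pouch (chick-meal) samples for one year
#'
#' Per-sample relative abundances are independent truncated normals around
#' the year's pouch profile, renormalised to sum to 1, then converted to
#' counts.
#'
#' @inheritParams gen_zoo_samples
#' @param year year key of `config$pouch_profiles`.
#' @export
gen_gular_samples <- function(config, year, n_samples, total_mean = 600) {
  .validate_config(config)
  key <- as.character(year)
  if (!key %in% names(config$pouch_profiles))
    stop("no pouch profile for year ", year)
  prof <- config$pouch_profiles[[key]]
  withr::with_seed(config$seed + .SEED_GULAR + as.integer(year), {
    rows <- vector("list", n_samples)
    for (i in seq_len(n_samples)) {
      ra <- pmax(0, rnorm(length(prof$mean), prof$mean, prof$sd))
      if (sum(ra) == 0) ra[which.max(prof$mean)] <- 1
      ra <- ra / sum(ra)
      total <- rpois(1, total_mean) + 1
      cnt <- as.integer(rmultinom(1, total, ra))
      rows[[i]] <- data.frame(
        sample_id = sprintf("gp%s_%02d", key, i),
        source = "gular_pouch", year = as.integer(year), stratum = "none",
        taxon = names(prof$mean), count = cnt,
        haul_depth = NA_real_, net_diameter = NA_real_
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate chick growth records over the linear growth window
#'
#' mass = intercept + slope * age + year effect + chick random intercept +
#' residual noise, with chicks weighed every second day from age 4 to 14.
#'
#' @param config [scenario_config()].
#' @param n_chicks total chicks (split evenly across `years`).
#' @param years vector of year labels.
#' @param year_effect additive mass offset (g) applied to every year after
#'   the first; 0 simulates the no-year-difference regime.
#' @return data.frame `chick_id`, `year`, `age`, `mass`, with the chick
#'   effects as attribute `truth`.
#' @export
gen_growth <- function(config, n_chicks, years = c(2012, 2014),
                       year_effect = 0) {
  .validate_config(config)
  if (n_chicks < 1) stop("n_chicks must be >= 1")
  withr::with_seed(config$seed + .SEED_GROWTH, {
    ages <- seq(4, 14, by = 2)
    yr <- rep(years, length.out = n_chicks)
    eff <- rnorm(n_chicks, 0, config$chick_sd)
    rows <- lapply(seq_len(n_chicks), function(i) {
      mass <- config$growth_intercept + config$growth_slope * ages +
        ifelse(yr[i] != years[1], year_effect, 0) + eff[i] +
        rnorm(length(ages), 0, config$resid_sd)
      data.frame(chick_id = sprintf("chick%03d", i), year = yr[i],
                 age = ages, mass = mass)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- data.frame(
      chick_id = sprintf("chick%03d", seq_len(n_chicks)),
      year = yr, effect = eff)
    out
  })
}

#' Construct a synthetic consolidated-ice polygon
#'
#' A rectangular >=80%-concentration ice area whose western edge lies
#' `edge_distance_km` east of the reference point (the feeding ground at
#' `target_distance` east of the colony by default). The near edge is
#' densified so projected distances to it stay accurate.
#'
#' @param config [scenario_config()].
#' @param edge_distance_km distance from the reference point to the ice
#'   edge, km; defaults to `config$ice_edge_distance`.
#' @param from `"apex"` (feeding ground) or `"colony"`.
#' @return closed ring matrix (lon, lat) usable with
#'   [distance_to_polygon()].
#' @export
gen_ice_polygon <- function(config, edge_distance_km = config$ice_edge_distance,
                            from = c("apex", "colony")) {
  from <- match.arg(from)
  x0 <- edge_distance_km + if (from == "apex") config$target_distance else 0
  ys <- seq(-400, 400, by = 10)
  ring <- rbind(
    cbind(x0, ys),               # densified western (near) edge
    cbind(x0 + 400, rev(ys))     # far edge
  )
  ring <- rbind(ring, ring[1, , drop = FALSE])
  ll <- unproject_aeq(ring[, 1], ring[, 2], config$colony)
  as.matrix(ll[, c("lon", "lat")])
}

#' Simulate a gridded sea-ice-concentration field
#'
#' Regular 12.5-km grid centred on the colony with i.i.d. noise around a
#' target mean concentration; used to exercise the regional-mean and trend
#' machinery.
#'
#' @param config [scenario_config()].
#' @param date date string for the field.
#' @param mean_sic target mean concentration, %.
#' @param noise_sd cell noise SD, %.
#' @param half_extent_km half-width of the simulated grid, km.
#' @return data.frame `date`, `lon`, `lat`, `sic`.
#' @export
gen_sic_field <- function(config, date, mean_sic, noise_sd = 2,
                          half_extent_km = 200) {
  .validate_config(config)
  day_key <- as.integer(as.Date(date)) %% 100000L
  withr::with_seed(config$seed + .SEED_SIC + day_key, {
    xs <- seq(-half_extent_km, half_extent_km, by = 12.5)
    grid <- expand.grid(x = xs, y = xs)
    ll <- unproject_aeq(grid$x, grid$y, config$colony)
    sic <- pmin(100, pmax(0, rnorm(nrow(grid), mean_sic, noise_sd)))
    data.frame(date = as.character(date), lon = ll$lon, lat = ll$lat,
               sic = sic)
  })
}

#' Write a full synthetic scenario to disk
#'
#' Emits every input the downstream modules read: GPS fixes, a TDR series,
#' at-sea and gular-pouch count tables, chick growth records, colony and
#' ice GeoJSON, and a JSON ground-truth sidecar (kept separate from the
#' data files). Output is byte-identical for a fixed config.
#'
#' @param config [scenario_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_scenario <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  tr <- gen_tracks(config)
  dv <- gen_dives(config)
  zoo <- do.call(rbind, lapply(names(config$community_profiles), function(s)
    gen_zoo_samples(config, s, n_samples = 10)))
  gp <- do.call(rbind, lapply(names(config$pouch_profiles), function(y)
    gen_gular_samples(config, y, n_samples = 20)))
  gr <- gen_growth(config, n_chicks = 50)
  ice <- gen_ice_polygon(config)

  write_fixes_csv(tr, p("fixes.csv"))
  write.csv(dv$series, p("tdr.csv"), row.names = FALSE, quote = FALSE)
  write.csv(zoo, p("zoo_at_sea.csv"), row.names = FALSE, quote = FALSE)
  write.csv(gp, p("gular_pouches.csv"), row.names = FALSE, quote = FALSE)
  write.csv(gr, p("chick_growth.csv"), row.names = FALSE, quote = FALSE)
  write_geojson(list(
    geojson_feature("Point", matrix(config$colony, ncol = 2),
                    list(name = "colony")),
    geojson_feature("Polygon", list(ice), list(name = "ice_80pct"))
  ), p("geography.geojson"))
  truth <- list(
    trips = attr(tr, "truth"),
    dives = dv$truth,
    growth = attr(gr, "truth"),
    seed = config$seed
  )
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = 10)
  invisible(c(fixes = p("fixes.csv"), tdr = p("tdr.csv"),
              zoo = p("zoo_at_sea.csv"), gular = p("gular_pouches.csv"),
              growth = p("chick_growth.csv"),
              geography = p("geography.geojson"), truth = p("truth.json")))
}
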