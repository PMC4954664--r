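# GPS-track processing: speed-threshold behavioural classification, trip
# segmentation and trip metrics, and distances to the colony and to the
# consolidated-ice edge.

#' Behavioural label for a segment speed
#'
#' Strict threshold rule: speeds strictly below `threshold_kmh` are
#' `forage_rest`, all others (including exactly the threshold) `travel`.
#'
#' @param speed_kmh numeric speeds; `NA` stays `NA`.
#' @param threshold_kmh classification threshold, km/h.
#' @return character vector.
#' @export
label_behaviour <- function(speed_kmh, threshold_kmh = 10) {
  ifelse(is.na(speed_kmh), NA_character_,
         ifelse(speed_kmh < threshold_kmh, "forage_rest", "travel"))
}

#' Segment speeds and behavioural classification
#'
#' Computes, for each fix after the first, the speed of the segment ending
#' at that fix (great-circle distance / elapsed time) and labels the fix
#' `forage_rest` when that speed is strictly below `threshold_kmh`, else
#' `travel`. At a 15-min sampling interval the segment speed is the only
#' available proxy for instantaneous speed. The comparison is strict: a
#' fix at exactly 10 km/h is `travel`.
#'
#' Segments spanning a gap longer than `max_gap_factor` times the median
#' sampling interval get `NA` speed and behaviour, and are excluded from
#' behaviour tallies.
#'
#' @param fixes data.frame with `bird_id` (optional), `t` (POSIXct), `lon`,
#'   `lat`, time-ordered within bird.
#' @param threshold_kmh classification threshold, km/h.
#' @param max_gap_factor gap tolerance as a multiple of the median
#'   interval; `Inf` disables gap handling.
#' @return the input with `speed_kmh` and `behaviour` columns; the first
#'   fix of each bird has both `NA`.
#' @export
compute_speeds <- function(fixes, threshold_kmh = 10, max_gap_factor = 3) {
  if (nrow(fixes) < 2) {
    warning("fewer than 2 fixes; no speeds computable")
    fixes$speed_kmh <- rep(NA_real_, nrow(fixes))
    fixes$behaviour <- rep(NA_character_, nrow(fixes))
    return(fixes)
  }
  if (is.null(fixes$bird_id)) fixes$bird_id <- "bird"
  out <- lapply(split(fixes, fixes$bird_id), function(d) {
    d <- d[order(d$t), , drop = FALSE]
    dt_h <- as.numeric(diff(as.numeric(d$t))) / 3600
    if (any(dt_h <= 0)) {
      bad <- which(dt_h <= 0)[1]
      stop("duplicate or non-increasing timestamp for bird '",
           d$bird_id[1], "' at ", format(d$t[bad + 1], tz = "UTC"))
    }
    dist <- haversine_km(d$lon[-nrow(d)], d$lat[-nrow(d)],
                         d$lon[-1], d$lat[-1])
    sp <- c(NA_real_, dist / dt_h)
    if (is.finite(max_gap_factor) && length(dt_h) > 0) {
      gap <- c(FALSE, dt_h > max_gap_factor * median(dt_h))
      sp[gap] <- NA_real_
    }
    d$speed_kmh <- sp
    d$behaviour <- label_behaviour(sp, threshold_kmh)
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Segment a labelled track into colony-to-colony foraging trips
#'
#' A trip is a maximal run of fixes outside the colony radius. It is
#' `complete` when flanked on both sides by fixes inside the radius; a
#' track that ends at sea yields an incomplete trip, which is excluded
#' from duration and path-length summaries downstream.
#'
#' @param fixes labelled fixes for one or more birds (see
#'   [compute_speeds()]).
#' @param colony c(lon, lat), degrees.
#' @param radius_km colony radius, km (default 1 km).
#' @return data.frame, one row per trip: `bird_id`, `trip`, `complete`,
#'   `start`, `end`, `duration_h`, `path_length_km`, `max_distance_km`,
#'   `n_fixes`; the per-trip fixes are kept in the list attribute
#'   `trip_fixes`.
#' @export
segment_trips <- function(fixes, colony, radius_km = 1) {
  if (radius_km <= 0) stop("radius_km must be > 0")
  if (is.null(fixes$bird_id)) fixes$bird_id <- "bird"
  trips <- list()
  trip_fixes <- list()
  for (d in split(fixes, fixes$bird_id)) {
    d <- d[order(d$t), , drop = FALSE]
    d$dist_col <- haversine_km(d$lon, d$lat, colony[1], colony[2])
    outside <- d$dist_col > radius_km
    r <- rle(outside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    k <- 0
    for (i in seq_along(r$values)) {
      if (!r$values[i]) next
      k <- k + 1
      idx <- starts[i]:ends[i]
      seg <- d[idx, , drop = FALSE]
      complete <- starts[i] > 1 && ends[i] < nrow(d)
      path <- if (nrow(seg) > 1)
        sum(haversine_km(seg$lon[-nrow(seg)], seg$lat[-nrow(seg)],
                         seg$lon[-1], seg$lat[-1])) else 0
      trips[[length(trips) + 1]] <- data.frame(
        bird_id = d$bird_id[1], trip = k, complete = complete,
        start = seg$t[1], end = seg$t[nrow(seg)],
        duration_h = as.numeric(difftime(seg$t[nrow(seg)], seg$t[1],
                                         units = "hours")),
        path_length_km = path,
        max_distance_km = max(seg$dist_col),
        n_fixes = nrow(seg)
      )
      trip_fixes[[length(trips)]] <- seg
    }
  }
  out <- if (length(trips)) do.call(rbind, trips) else
    data.frame(bird_id = character(0), trip = integer(0),
               complete = logical(0), start = as.POSIXct(character(0)),
               end = as.POSIXct(character(0)), duration_h = numeric(0),
               path_length_km = numeric(0), max_distance_km = numeric(0),
               n_fixes = integer(0))
  rownames(out) <- NULL
  attr(out, "trip_fixes") <- trip_fixes
  out
}

#' Summarise trips per group and compare two groups
#'
#' Mean and SD of maximum colony distance, trip duration and path length
#' per group (typically year), using complete trips only for duration and
#' path length. When exactly two groups are present, each metric is also
#' compared with a two-sided Wilcoxon rank-sum test (exact for combined
#' n <= 20, normal approximation with continuity correction above). The
#' reported W follows the first-group rank-sum convention of
#' [stats::wilcox.test()], stated in the output.
#'
#' @param trips output of [segment_trips()].
#' @param group vector assigning each trip to a group (e.g. year).
#' @return list with `summary` (per group x metric) and `tests` (per
#'   metric W and p, `NULL` unless exactly 2 groups with complete trips).
#' @export
trip_summary <- function(trips, group) {
  group <- as.character(group)
  metrics <- c(max_distance_km = "max_distance_km",
               duration_h = "duration_h",
               path_length_km = "path_length_km")
  rows <- list()
  for (g in unique(group)) {
    sub <- trips[group == g, , drop = FALSE]
    compl <- sub[sub$complete, , drop = FALSE]
    if (nrow(compl) == 0)
      warning("group '", g, "' has no complete trips; summaries are NA")
    for (m in names(metrics)) {
      vals <- if (m == "max_distance_km") sub[[m]] else compl[[m]]
      rows[[length(rows) + 1]] <- data.frame(
        group = g, metric = m, n = length(vals),
        mean = if (length(vals)) mean(vals) else NA_real_,
        sd = if (length(vals) > 1) sd(vals) else NA_real_
      )
    }
  }
  summary <- do.call(rbind, rows)
  tests <- NULL
  gs <- unique(group)
  if (length(gs) == 2) {
    tests <- lapply(names(metrics), function(m) {
      keep <- if (m == "max_distance_km") rep(TRUE, nrow(trips)) else
        trips$complete
      sub <- trips[keep, , drop = FALSE]
      grp <- group[keep]
      x <- sub[[m]][grp == gs[1]]
      y <- sub[[m]][grp == gs[2]]
      if (!length(x) || !length(y)) {
        warning("skipping Wilcoxon for ", m, ": empty group")
        return(data.frame(metric = m, W = NA_real_, p = NA_real_))
      }
      exact <- (length(x) + length(y)) <= 20 &&
        !anyDuplicated(c(x, y))
      wt <- suppressWarnings(
        wilcox.test(x, y, exact = exact, correct = TRUE))
      data.frame(metric = m, W = unname(wt$statistic), p = wt$p.value)
    })
    tests <- do.call(rbind, tests)
    attr(tests, "convention") <-
      paste0("W = rank sum of group '", gs[1],
             "' minus its minimum possible value (stats::wilcox.test)")
  }
  list(summary = summary, tests = tests)
}

#' Distance from positions to a polygon (e.g. the >=80% ice area)
#'
#' Points inside or on the polygon get 0; others the minimum distance to
#' its boundary. Computation happens in a local azimuthal-equidistant
#' frame centred on `center` (default: centroid of the query points), so
#' distances are effectively great-circle at regional scale.
#'
#' @param lon,lat point coordinates, degrees.
#' @param polygon ring matrix (lon, lat) or list of rings.
#' @param center optional c(lon, lat) projection centre.
#' @return distances in km.
#' @export
distance_to_polygon <- function(lon, lat, polygon, center = NULL) {
  rings <- if (is.list(polygon) && !is.data.frame(polygon)) polygon else list(polygon)
  rings <- lapply(rings, as.matrix)
  if (!length(rings) || any(vapply(rings, nrow, 0L) < 3))
    stop("polygon must have at least one ring of >= 3 vertices")
  if (is.null(center)) center <- c(mean(lon), mean(lat))
  pts <- project_aeq(lon, lat, center)
  prings <- lapply(rings, function(r) {
    pr <- project_aeq(r[, 1], r[, 2], center)
    cbind(pr$x, pr$y)
  })
  d <- .dist_to_rings(pts$x, pts$y, prings)
  inside <- point_in_polygon(pts$x, pts$y, prings)
  ifelse(inside, 0, d)
}
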