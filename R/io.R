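#' Read a GPS fix table
#'
#' Expected columns: `bird_id`, `timestamp` (ISO-8601, UTC), `lon`, `lat`.
#' Timestamps are parsed to POSIXct; fixes are sorted within bird and basic
#' range checks are applied.
#'
#' @param path CSV file.
#' @return data.frame of fixes.
#' @export
read_fixes_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird_id", "timestamp", "lon", "lat")
  if (!all(need %in% names(d)))
    stop("fixes CSV must have columns: ", paste(need, collapse = ", "))
  d$t <- as.POSIXct(d$timestamp, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(d$t)) stop("unparseable timestamps in ", path)
  if (any(abs(d$lat) > 90) || any(d$lon < -180 | d$lon > 180))
    stop("lon/lat out of range in ", path)
  d <- d[order(d$bird_id, d$t), c("bird_id", "t", "lon", "lat")]
  rownames(d) <- NULL
  d
}

#' @rdname read_fixes_csv
#' @param fixes data.frame with `bird_id`, `t`, `lon`, `lat`.
#' @export
write_fixes_csv <- function(fixes, path) {
  out <- data.frame(
    bird_id = fixes$bird_id,
    timestamp = format(fixes$t, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    lon = sprintf("%.6f", fixes$lon),
    lat = sprintf("%.6f", fixes$lat)
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a depth-record table
#'
#' Expected columns: `tag_id`, `time_s` (seconds from record start) or
#' `timestamp`, `raw_depth`, `tag_model`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_dive_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!"raw_depth" %in% names(d)) stop("dive CSV needs a raw_depth column")
  if ("timestamp" %in% names(d) && !"time_s" %in% names(d)) {
    tt <- as.POSIXct(d$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    d$time_s <- as.numeric(tt) - as.numeric(tt[1])
  }
  d
}

#' Read a zooplankton / gular-pouch count table
#'
#' Long format: `sample_id`, `source` (gular_pouch | at_sea), `year`,
#' `stratum`, `taxon`, `count`, plus optional `stage`, `haul_depth`,
#' `net_diameter`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_counts_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "taxon", "count")
  if (!all(need %in% names(d)))
    stop("counts CSV must have columns: ", paste(need, collapse = ", "))
  if (any(d$count < 0)) stop("negative counts in ", path)
  d
}

# ---- minimal GeoJSON support (points, linestrings, polygons) ----

#' Read a GeoJSON file
#'
#' Supports FeatureCollection / Feature / bare geometry with Point,
#' LineString, Polygon and MultiPolygon geometries. Returns a list of
#' features, each `list(type=, coords=, properties=)`; polygon coords are a
#' list of rings (two-column matrices, lon/lat).
#'
#' @param path GeoJSON file.
#' @return list of features.
#' @export
read_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- switch(g$type,
    FeatureCollection = g$features,
    Feature = list(g),
    list(list(type = "Feature", geometry = g, properties = list()))
  )
  lapply(feats, function(f) {
    geom <- f$geometry
    coords <- switch(geom$type,
      Point = matrix(unlist(geom$coordinates), ncol = 2),
      LineString = do.call(rbind, lapply(geom$coordinates, unlist)),
      Polygon = lapply(geom$coordinates, function(r)
        do.call(rbind, lapply(r, unlist))),
      MultiPolygon = unlist(lapply(geom$coordinates, function(poly)
        lapply(poly, function(r) do.call(rbind, lapply(r, unlist)))),
        recursive = FALSE),
      stop("unsupported geometry type: ", geom$type)
    )
    list(type = geom$type, coords = coords,
         properties = if (is.null(f$properties)) list() else f$properties)
  })
}

#' Write geometries to GeoJSON
#'
#' @param features list of features as returned by [read_geojson()], or
#'   built with [geojson_feature()].
#' @param path output file.
#' @export
write_geojson <- function(features, path) {
  to_coords <- function(type, coords) {
    switch(type,
      Point = as.numeric(coords[1, ]),
      LineString = lapply(seq_len(nrow(coords)), function(i)
        as.numeric(coords[i, ])),
      Polygon = lapply(coords, function(r) {
        r <- as.matrix(r)
        if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
        lapply(seq_len(nrow(r)), function(i) as.numeric(r[i, ]))
      }),
      stop("unsupported geometry type: ", type)
    )
  }
  fc <- list(
    type = "FeatureCollection",
    features = lapply(features, function(f) list(
      type = "Feature",
      properties = if (length(f$properties)) f$properties else
        structure(list(), names = character(0)),
      geometry = list(type = f$type, coordinates = to_coords(f$type, f$coords))
    ))
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 8, pretty = FALSE)
  invisible(path)
}

#' @rdname write_geojson
#' @param type "Point", "LineString" or "Polygon".
#' @param coords two-column matrix (Point/LineString) or list of ring
#'   matrices (Polygon).
#' @param properties named list.
#' @export
geojson_feature <- function(type, coords, properties = list()) {
  if (type %in% c("Point", "LineString")) coords <- as.matrix(coords)
  list(type = type, coords = coords, properties = properties)
}
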