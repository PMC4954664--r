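#' Great-circle distance between points (haversine)
#'
#' Spherical distance on an earth of radius 6371 km. Inputs are recycled;
#' all angles in decimal degrees (WGS84 lon/lat).
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees.
#' @return distance(s) in km.
#' @export
#' @examples
#' haversine_km(-21.583, 70.733, -21.0, 70.733)
haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * .R_EARTH_KM * asin(sqrt(a))
}

#' Azimuthal-equidistant projection centred on a reference point
#'
#' Projects lon/lat to a local planar frame (km east, km north) in which
#' distances from the centre are exact on the sphere and distortion stays
#' negligible at the regional (few hundred km) scale this package works at.
#' `unproject_aeq()` is the exact inverse.
#'
#' @param lon,lat coordinates in degrees.
#' @param center c(lon, lat) of the projection centre.
#' @return `project_aeq`: data.frame with columns `x`, `y` (km);
#'   `unproject_aeq`: data.frame with `lon`, `lat` (degrees).
#' @export
project_aeq <- function(lon, lat, center) {
  to_rad <- pi / 180
  lam0 <- center[1] * to_rad
  phi0 <- center[2] * to_rad
  lam <- lon * to_rad
  phi <- lat * to_rad
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- .R_EARTH_KM * k * cos(phi) * sin(lam - lam0)
  y <- .R_EARTH_KM * k *
    (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  data.frame(x = x, y = y)
}

#' @rdname project_aeq
#' @param x,y planar coordinates in km.
#' @export
unproject_aeq <- function(x, y, center) {
  to_rad <- pi / 180
  lam0 <- center[1] * to_rad
  phi0 <- center[2] * to_rad
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / .R_EARTH_KM
  phi <- ifelse(
    rho < 1e-12, phi0,
    asin(cos(c_ang) * sin(phi0) + (y / pmax(rho, 1e-12)) * sin(c_ang) * cos(phi0))
  )
  lam <- lam0 + atan2(
    x * sin(c_ang),
    rho * cos(phi0) * cos(c_ang) - y * sin(phi0) * sin(c_ang)
  )
  lam <- ifelse(rho < 1e-12, lam0, lam)
  data.frame(lon = lam / to_rad, lat = phi / to_rad)
}

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorised ray casting. A polygon is a two-column matrix of vertices
#' (closed or open ring); a list of rings is treated with the even-odd rule,
#' so holes are supported. Points exactly on an edge count as inside.
#'
#' @param px,py point coordinates.
#' @param polygon two-column matrix, or list of such matrices (rings).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, polygon) {
  rings <- if (is.list(polygon) && !is.data.frame(polygon)) polygon else list(polygon)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (ring in rings) {
    ring <- as.matrix(ring)
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    n <- nrow(ring)
    if (n < 3) stop("polygon ring needs at least 3 vertices")
    j <- n
    for (i in seq_len(n)) {
      xi <- ring[i, 1]; yi <- ring[i, 2]
      xj <- ring[j, 1]; yj <- ring[j, 2]
      # edge membership (within numerical tolerance)
      dx <- xj - xi; dy <- yj - yi
      len2 <- dx^2 + dy^2
      if (len2 > 0) {
        t <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2))
        d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
        on_edge <- on_edge | d2 < 1e-18
      } else {
        on_edge <- on_edge | ((px - xi)^2 + (py - yi)^2 < 1e-18)
      }
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
      j <- i
    }
  }
  inside | on_edge
}

# minimum distance from points to the boundary (segments) of a set of rings
.dist_to_rings <- function(px, py, rings) {
  if (!is.list(rings) || is.data.frame(rings)) rings <- list(rings)
  best <- rep(Inf, length(px))
  for (ring in rings) {
    ring <- as.matrix(ring)
    if (nrow(ring) < 2) next
    if (!all(ring[1, ] == ring[nrow(ring), ]))
      ring <- rbind(ring, ring[1, ])
    for (i in seq_len(nrow(ring) - 1)) {
      xi <- ring[i, 1]; yi <- ring[i, 2]
      dx <- ring[i + 1, 1] - xi; dy <- ring[i + 1, 2] - yi
      len2 <- dx^2 + dy^2
      t <- if (len2 == 0) rep(0, length(px)) else
        pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2))
      d2 <- (px - (xi + t * dx))^2 + (py - (yi + t * dy))^2
      best <- pmin(best, d2)
    }
  }
  sqrt(best)
}

# signed shoelace area of one ring (planar, km^2)
.ring_area <- function(ring) {
  ring <- as.matrix(ring)
  if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  0.5 * sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)
}
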