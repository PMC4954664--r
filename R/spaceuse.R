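# Kernel utilization distributions of foraging/resting positions, volume
# contours, and overlap of core areas with each other and with the
# shelf-break band. All geometry is planar (km), i.e. positions are
# expected in a local projection such as project_aeq().

#' Reference ("ad hoc") kernel bandwidth
#'
#' The bivariate reference rule used by classic home-range software:
#' h = sigma * n^(-1/6) with sigma = sqrt((var(x) + var(y)) / 2).
#'
#' @param x,y point coordinates, km.
#' @return bandwidth in km.
#' @export
adhoc_bandwidth <- function(x, y) {
  n <- length(x)
  sigma <- sqrt((var(x) + var(y)) / 2)
  sigma * n^(-1 / 6)
}

#' Kernel utilization distribution on a regular grid
#'
#' Bivariate Gaussian product-kernel density estimate, normalised so the
#' discrete mass (density x cell area) sums to 1.
#'
#' @param x,y projected point coordinates, km.
#' @param bandwidth kernel SD in km; default [adhoc_bandwidth()].
#' @param grid_n cells per axis.
#' @param pad extent padding in bandwidths beyond the point bounding box.
#' @return object of class `auk_ud`: list with `x`, `y` (cell-centre
#'   coordinates), `z` (density matrix, x by y), `cell_km` (dx, dy),
#'   `bandwidth`, `n`.
#' @export
kde_ud <- function(x, y, bandwidth = NULL, grid_n = 200, pad = 3) {
  n <- length(x)
  if (n < 5) stop("need at least 5 points for a utilization distribution")
  if (var(x) + var(y) == 0)
    stop("all points identical; supply a positive minimum bandwidth")
  if (is.null(bandwidth)) bandwidth <- adhoc_bandwidth(x, y)
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  xr <- range(x) + c(-1, 1) * pad * bandwidth
  yr <- range(y) + c(-1, 1) * pad * bandwidth
  gx <- seq(xr[1], xr[2], length.out = grid_n)
  gy <- seq(yr[1], yr[2], length.out = grid_n)
  # product kernel: outer sums of univariate normal densities
  kx <- outer(gx, x, function(g, p) dnorm(g, p, bandwidth))
  ky <- outer(gy, y, function(g, p) dnorm(g, p, bandwidth))
  z <- (kx %*% t(ky)) / n
  dx <- gx[2] - gx[1]
  dy <- gy[2] - gy[1]
  z <- z / (sum(z) * dx * dy) # renormalise mass clipped by the grid edge
  structure(list(x = gx, y = gy, z = z, cell_km = c(dx, dy),
                 bandwidth = bandwidth, n = n),
            class = "auk_ud")
}

#' @export
print.auk_ud <- function(x, ...) {
  cat(sprintf(
    "Utilization distribution: %d x %d grid, cell %.3f x %.3f km, h = %.3f km, n = %d\n",
    length(x$x), length(x$y), x$cell_km[1], x$cell_km[2], x$bandwidth, x$n))
  invisible(x)
}

#' Volume contour (core-area) of a utilization distribution
#'
#' Grid cells are ranked by density; the smallest set of top cells whose
#' cumulative mass reaches `level` defines the region (the paper-standard
#' "volume" contour, 75% by default for the core foraging/resting area).
#' The region is held as a cell mask (authoritative for area and overlap)
#' and polygonised for export.
#'
#' @param ud an `auk_ud`.
#' @param level probability level in (0, 1).
#' @return object of class `auk_contour`: `mask` (logical matrix),
#'   `level`, `area_km2`, `mass` (contained probability), the grid
#'   vectors, and `polygons` (list of boundary rings in km).
#' @export
volume_contour <- function(ud, level = 0.75) {
  if (!inherits(ud, "auk_ud")) stop("ud must be an auk_ud")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  cell_area <- prod(ud$cell_km)
  mass <- ud$z * cell_area
  ord <- order(ud$z, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  k <- which(cum >= level)[1]
  mask <- matrix(FALSE, nrow(ud$z), ncol(ud$z))
  mask[ord[seq_len(k)]] <- TRUE
  thr <- ud$z[ord[k]]
  polys <- contourLines(ud$x, ud$y, ud$z, levels = thr)
  polys <- lapply(polys, function(p) cbind(p$x, p$y))
  structure(list(mask = mask, level = level,
                 area_km2 = k * cell_area, mass = cum[k],
                 x = ud$x, y = ud$y, cell_km = ud$cell_km,
                 polygons = polys),
            class = "auk_contour")
}

#' @export
print.auk_contour <- function(x, ...) {
  cat(sprintf("%.0f%% volume contour: area %.1f km2, contained mass %.4f\n",
              100 * x$level, x$area_km2, x$mass))
  invisible(x)
}

# logical membership of arbitrary points in a region
# region: auk_contour (cell mask) or polygon ring(s)
.region_membership <- function(px, py, region) {
  if (inherits(region, "auk_contour")) {
    dx <- region$cell_km[1]; dy <- region$cell_km[2]
    ix <- round((px - region$x[1]) / dx) + 1
    iy <- round((py - region$y[1]) / dy) + 1
    ok <- ix >= 1 & ix <= length(region$x) & iy >= 1 & iy <= length(region$y)
    out <- rep(FALSE, length(px))
    out[ok] <- region$mask[cbind(ix[ok], iy[ok])]
    out
  } else {
    point_in_polygon(px, py, region)
  }
}

.region_bbox <- function(region) {
  if (inherits(region, "auk_contour")) {
    idx <- which(region$mask, arr.ind = TRUE)
    dx <- region$cell_km[1]; dy <- region$cell_km[2]
    c(min(region$x[idx[, 1]]) - dx / 2, max(region$x[idx[, 1]]) + dx / 2,
      min(region$y[idx[, 2]]) - dy / 2, max(region$y[idx[, 2]]) + dy / 2)
  } else {
    rings <- if (is.list(region) && !is.data.frame(region)) region else
      list(region)
    m <- do.call(rbind, lapply(rings, as.matrix))
    c(range(m[, 1]), range(m[, 2]))
  }
}

#' Overlap between two regions (core areas and/or a habitat band)
#'
#' Areas of each region, their intersection and union, and the overlap
#' percentage under all three denominators (region A, region B, union).
#' "Percentage of overlap" is ambiguous in the field; all three
#' conventions are always reported. Geometry is evaluated on a fine
#' common grid (cell-mask regions keep their native cells; polygons are
#' rasterised by centre-point membership).
#'
#' @param a,b `auk_contour` objects or polygon ring(s) (matrix or list of
#'   matrices, km).
#' @param grid_n resolution per axis of the common evaluation grid.
#' @return data.frame with `area_a`, `area_b`, `area_intersection`,
#'   `area_union` (km2) and `pct_of_a`, `pct_of_b`, `pct_of_union`.
#' @export
overlap <- function(a, b, grid_n = 600) {
  ba <- .region_bbox(a)
  bb <- .region_bbox(b)
  xr <- c(min(ba[1], bb[1]), max(ba[2], bb[2]))
  yr <- c(min(ba[3], bb[3]), max(ba[4], bb[4]))
  if (diff(xr) <= 0 || diff(yr) <= 0) stop("degenerate region extents")
  gx <- seq(xr[1], xr[2], length.out = grid_n)
  gy <- seq(yr[1], yr[2], length.out = grid_n)
  # offset by half a cell: sample at cell centres
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  pts <- expand.grid(x = gx + dx / 2, y = gy + dy / 2)
  in_a <- .region_membership(pts$x, pts$y, a)
  in_b <- .region_membership(pts$x, pts$y, b)
  cell <- dx * dy
  area_a <- sum(in_a) * cell
  area_b <- sum(in_b) * cell
  inter <- sum(in_a & in_b) * cell
  uni <- sum(in_a | in_b) * cell
  data.frame(
    area_a = area_a, area_b = area_b,
    area_intersection = inter, area_union = uni,
    pct_of_a = if (area_a > 0) 100 * inter / area_a else 0,
    pct_of_b = if (area_b > 0) 100 * inter / area_b else 0,
    pct_of_union = if (uni > 0) 100 * inter / uni else 0
  )
}

#' Shelf-break band polygon from two isobath polylines
#'
#' Builds the band between the 500-m and 1500-m isobaths by joining the
#' two polylines end-to-end into a single closed ring. Both polylines must
#' run in the same direction (e.g. south to north); the second is
#' reversed internally.
#'
#' @param iso_a,iso_b two-column polyline matrices (projected km or
#'   lon/lat, used consistently downstream).
#' @return closed ring matrix.
#' @export
band_polygon <- function(iso_a, iso_b) {
  iso_a <- as.matrix(iso_a)
  iso_b <- as.matrix(iso_b)
  if (nrow(iso_a) < 2 || nrow(iso_b) < 2) stop("isobath polylines too short")
  ring <- rbind(iso_a, iso_b[rev(seq_len(nrow(iso_b))), , drop = FALSE])
  ring <- rbind(ring, ring[1, , drop = FALSE])
  if (abs(.ring_area(ring)) <= 0) stop("degenerate band polygon")
  ring
}

#' Longitude-binned sighting counts relative to the isobaths
#'
#' Sums at-sea counts per longitude bin and labels each bin by its
#' position relative to the 500-m and 1500-m isobath longitudes (shelf on
#' the far side of the 500-m isobath from the 1500-m one, band in
#' between, ocean beyond).
#'
#' @param lon per-observation longitude, degrees.
#' @param count individuals per observation.
#' @param bin_width bin width, degrees.
#' @param isobath_lons c(lon of 500-m isobath, lon of 1500-m isobath).
#' @return data.frame `bin_mid`, `count`, `zone`.
#' @export
bin_sightings <- function(lon, count, bin_width = 0.1,
                          isobath_lons = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (!length(lon))
    return(data.frame(bin_mid = numeric(0), count = numeric(0),
                      zone = character(0)))
  lo <- floor(min(lon) / bin_width) * bin_width
  hi <- ceiling(max(lon) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  idx <- findInterval(lon, breaks, rightmost.closed = TRUE)
  tot <- tapply(count, factor(idx, levels = seq_len(length(breaks) - 1)), sum)
  tot[is.na(tot)] <- 0
  mid <- breaks[-length(breaks)] + bin_width / 2
  zone <- rep(NA_character_, length(mid))
  if (!is.null(isobath_lons)) {
    l500 <- isobath_lons[1]; l1500 <- isobath_lons[2]
    toward_ocean <- sign(l1500 - l500)
    rel <- (mid - l500) * toward_ocean
    rel2 <- (mid - l1500) * toward_ocean
    zone <- ifelse(rel < 0, "continental_shelf",
                   ifelse(rel2 <= 0, "shelf_break", "open_ocean"))
  }
  data.frame(bin_mid = mid, count = as.numeric(tot), zone = zone)
}
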