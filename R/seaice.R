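# Regional sea-ice-concentration summaries and the interannual trend test.

#' Rectangular analysis region around a point
#'
#' A width x height km rectangle centred on the colony, expressed as a
#' lon/lat ring via the local azimuthal-equidistant frame. Default
#' 150 x 200 km (east-west x north-south).
#'
#' @param center c(lon, lat), degrees.
#' @param width_km,height_km rectangle dimensions, km.
#' @return closed ring matrix (lon, lat).
#' @export
region_rectangle <- function(center, width_km = 150, height_km = 200) {
  w <- width_km / 2; h <- height_km / 2
  xs <- c(seq(-w, w, length.out = 20), rep(w, 20),
          seq(w, -w, length.out = 20), rep(-w, 20))
  ys <- c(rep(-h, 20), seq(-h, h, length.out = 20),
          rep(h, 20), seq(h, -h, length.out = 20))
  ll <- unproject_aeq(xs, ys, center)
  ring <- as.matrix(ll[, c("lon", "lat")])
  rbind(ring, ring[1, , drop = FALSE])
}

#' Regional mean sea-ice concentration over a window
#'
#' Unweighted mean concentration over all grid cells inside the region
#' and all dates inside the window; missing cells are ignored and
#' counted. Cells are equally weighted (near-equal-area polar grids);
#' cosine-latitude area weighting is available via `area_weight`.
#'
#' @param grids long data.frame `date`, `lon`, `lat`, `sic` (% in
#'   [0, 100], NA allowed).
#' @param region lon/lat ring (e.g. [region_rectangle()]).
#' @param window c(first, last) dates (anything `as.Date` accepts);
#'   `NULL` uses all dates.
#' @param area_weight weight cells by cos(latitude).
#' @return one-row data.frame `mean_sic`, `n_cells`, `n_missing`,
#'   `n_days`.
#' @export
regional_mean <- function(grids, region, window = NULL,
                          area_weight = FALSE) {
  d <- grids
  d$date <- as.Date(d$date)
  if (!is.null(window)) {
    window <- as.Date(window)
    d <- d[d$date >= window[1] & d$date <= window[2], , drop = FALSE]
  }
  if (!nrow(d)) stop("no grid dates inside the window")
  cen <- c(mean(range(region[, 1])), mean(range(region[, 2])))
  p <- project_aeq(d$lon, d$lat, cen)
  pr <- project_aeq(region[, 1], region[, 2], cen)
  inside <- point_in_polygon(p$x, p$y, cbind(pr$x, pr$y))
  d <- d[inside, , drop = FALSE]
  if (!nrow(d)) stop("region does not intersect the grid")
  if (any(!is.na(d$sic) & (d$sic < 0 | d$sic > 100)))
    stop("sea-ice concentration outside [0, 100]")
  miss <- is.na(d$sic)
  val <- d$sic[!miss]
  w <- if (area_weight) cos(d$lat[!miss] * pi / 180) else
    rep(1, length(val))
  data.frame(mean_sic = weighted.mean(val, w),
             n_cells = length(val), n_missing = sum(miss),
             n_days = length(unique(d$date)))
}

#' Linear interannual trend in a regional series
#'
#' OLS of the yearly mean concentration on year; reports the slope
#' (%/yr), t = slope / SE with df = n - 2, and the two-sided p.
#'
#' @param year numeric years.
#' @param mean_sic yearly mean concentrations, %.
#' @return one-row data.frame `slope`, `se`, `t`, `df`, `p`.
#' @export
trend_test <- function(year, mean_sic) {
  if (length(year) < 3) stop("need >= 3 years")
  if (length(unique(mean_sic)) == 1)
    stop("constant series: slope 0, t undefined")
  fit <- lm(mean_sic ~ year)
  s <- coef(summary(fit))
  data.frame(slope = s["year", "Estimate"], se = s["year", "Std. Error"],
             t = s["year", "t value"], df = fit$df.residual,
             p = s["year", "Pr(>|t|)"])
}
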