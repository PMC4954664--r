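# Depth calibration by tag model, dive detection, and dive metrics.

# pressure-chamber cross-calibration of the DST micro-TD tag, which
# underestimates true depth
.STAR_ODDI_SLOPE <- 1.0473
.STAR_ODDI_INTERCEPT <- 0.4498

#' Calibrate raw depth readings by tag model
#'
#' DST micro-TD (Star Oddi) tags underestimate true depth; their readings
#' are corrected with the affine pressure-chamber calibration
#' depth = 1.0473 * raw + 0.4498 (m). Other tag models are returned
#' unchanged.
#'
#' @param raw raw depth, m.
#' @param tag_model tag model string; `"DST micro-TD"` (or `"Star Oddi"`)
#'   triggers the correction.
#' @param strict if `TRUE`, an unrecognised model is an error instead of
#'   identity-with-warning.
#' @return calibrated depth, m.
#' @export
#' @examples
#' calibrate_depth(10, "DST micro-TD") # 10.9228
#' calibrate_depth(10, "G5")           # 10
calibrate_depth <- function(raw, tag_model, strict = FALSE) {
  if (any(!is.finite(raw))) stop("raw depth must be finite")
  known <- c("DST micro-TD", "Star Oddi", "G5", "LUL")
  if (tag_model %in% c("DST micro-TD", "Star Oddi"))
    return(.STAR_ODDI_SLOPE * raw + .STAR_ODDI_INTERCEPT)
  if (!tag_model %in% known) {
    if (strict) stop("unknown tag model: ", tag_model)
    warning("unknown tag model '", tag_model, "'; depth left uncalibrated")
  }
  raw
}

#' Detect dives in a depth time series and summarise them
#'
#' A dive is a maximal run of samples at or below `-min_depth`-equivalent
#' (depth >= `min_depth`) lasting at least `min_duration`. Duration is
#' measured from the first to one past the last sample of the run (i.e.
#' run length x sampling interval), which makes detection invariant to
#' the sampling interval for dives spanning >= 3 samples.
#'
#' @param time_s sample times, s (strictly increasing, regular).
#' @param depth calibrated depth, m (positive down).
#' @param min_depth detection threshold, m.
#' @param min_duration minimum dive duration, s.
#' @return list: `dives` (data.frame `start_s`, `end_s`, `duration`,
#'   `max_depth`) and `summary` (`n_dives`, `rate_per_24h`,
#'   `mean_max_depth`, `mean_duration`, `span_s`).
#' @export
detect_dives <- function(time_s, depth, min_depth = 2, min_duration = 8) {
  if (length(time_s) != length(depth)) stop("time_s and depth differ in length")
  if (is.unsorted(time_s, strictly = TRUE)) stop("timestamps must be strictly increasing")
  dt <- diff(time_s)
  interval <- median(dt)
  under <- depth >= min_depth
  r <- rle(under)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths * interval >= min_duration)
  dives <- data.frame(start_s = time_s[starts[keep]],
                      end_s = time_s[ends[keep]] + interval,
                      duration = r$lengths[keep] * interval,
                      max_depth = vapply(which(keep), function(i)
                        max(depth[starts[i]:ends[i]]), 0))
  rownames(dives) <- NULL
  span <- time_s[length(time_s)] - time_s[1] + interval
  list(
    dives = dives,
    summary = data.frame(
      n_dives = nrow(dives),
      rate_per_24h = nrow(dives) * 86400 / span,
      mean_max_depth = if (nrow(dives)) mean(dives$max_depth) else NA_real_,
      mean_duration = if (nrow(dives)) mean(dives$duration) else NA_real_,
      span_s = span
    )
  )
}
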