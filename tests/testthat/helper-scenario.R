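# shared fixtures and small independent oracles

base_config <- function(seed = 1, ...) scenario_config(seed = seed, ...)

# Rand index between two partitions (pair-counting, computed from scratch)
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  up <- upper.tri(same_a)
  mean(same_a[up] == same_b[up])
}

# forage/rest positions of a synthetic scenario, projected to km
forage_points <- function(cfg) {
  tr <- gen_tracks(cfg)
  lf <- compute_speeds(tr)
  fr <- lf[!is.na(lf$behaviour) & lf$behaviour == "forage_rest", ]
  project_aeq(fr$lon, fr$lat, cfg$colony)
}

# unit square ring with lower-left corner at (x0, y0)
unit_square <- function(x0 = 0, y0 = 0) {
  cbind(c(x0, x0 + 1, x0 + 1, x0, x0), c(y0, y0, y0 + 1, y0 + 1, y0))
}
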