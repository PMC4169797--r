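# shared fixtures: analytic contours, small phantom specs, ROC oracle

circle_contour <- function(r, n = 120, center = c(0, 0)) {
  th <- (seq_len(n) - 1) * 2 * pi / n
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

# the worked incompressible example: 20 -> 15 mm endo, 30 mm epi
example_spec <- function(...) {
  lv_phantom_spec(
    ed_endo_radius_mm = 20, ed_epi_radius_mm = 30,
    ed_to_es_endo_fraction = 0.75, frames_per_cycle = 20,
    ...
  )
}

# uniform-velocity field over a small raster (cm/s)
uniform_velocity_field <- function(vx_cms, vz_cms, n_frames = 20,
                                   cycle_duration_s = 1) {
  x <- seq(-40, 40, by = 2)
  z <- seq(-10, 90, by = 2)
  times <- (seq_len(n_frames) - 1) * cycle_duration_s / n_frames
  dims <- c(length(x), length(z), n_frames)
  velocity_field(
    array(vx_cms, dims), array(vz_cms, dims),
    x_mm = x, z_mm = z, times = times,
    cycle_duration_s = cycle_duration_s
  )
}

# exhaustive-threshold ROC oracle: every midpoint between sorted unique
# values plus the two extremes, same tie-breaking as roc_scan
roc_oracle <- function(values, positive, direction = "below") {
  uv <- sort(unique(values))
  cand <- c(uv[1] - 1, (uv[-length(uv)] + uv[-1]) / 2, uv[length(uv)] + 1)
  pos_v <- values[positive]
  neg_v <- values[!positive]
  if (direction == "below") {
    sens <- vapply(cand, function(h) mean(pos_v < h), numeric(1))
    spec <- vapply(cand, function(h) mean(neg_v >= h), numeric(1))
  } else {
    sens <- vapply(cand, function(h) mean(pos_v > h), numeric(1))
    spec <- vapply(cand, function(h) mean(neg_v <= h), numeric(1))
  }
  youden <- sens + spec - 1
  best <- which(youden > max(youden) - 1e-12)
  best <- best[spec[best] > max(spec[best]) - 1e-12]
  opt <- best[ceiling(length(best) / 2)]
  list(
    youden = youden[opt], sensitivity = sens[opt], specificity = spec[opt],
    threshold = cand[opt]
  )
}

# shoelace area of a closed polygon
polygon_area <- function(p) {
  x <- p[, 1]
  y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
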