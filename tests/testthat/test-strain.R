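test_that("constant velocity integrates to the expected displacement", {
  vf <- uniform_velocity_field(1, 0, n_frames = 20) # 1 cm/s, dt = 0.05 s
  traj <- track_points(cbind(0, 40), vf, substeps = 1)
  # one frame step: 1 cm/s * 0.05 s = 0.5 mm, before closure correction
  expect_equal(traj$raw_positions[1, 1, 2] - traj$raw_positions[1, 1, 1], 0.5,
    tolerance = 1e-9
  )
  expect_equal(traj$raw_positions[1, 2, 2], 40)
})

test_that("zero velocity gives constant trajectories with zero closure error", {
  vf <- uniform_velocity_field(0, 0)
  traj <- track_points(cbind(c(-5, 0, 5), c(30, 40, 50)), vf)
  expect_equal(max(traj$closure_error_mm), 0)
  expect_true(all(apply(traj$positions, 3, identical, traj$positions[, , 1])))
})

test_that("points leaving the raster and velocities above venc are flagged", {
  vf <- uniform_velocity_field(10, 0, n_frames = 10) # 10 cm/s -> 100 mm/cycle
  expect_error(track_points(cbind(30, 40), vf), "out-of-field")
  vf2 <- uniform_velocity_field(30, 0, n_frames = 10)
  vf2$venc_cm_s <- 20
  expect_warning(
    try(track_points(cbind(-35, 40), vf2), silent = TRUE),
    "aliasing"
  )
})

# build a trajectory_set directly from analytic point positions
manual_traj <- function(frames_list) {
  n <- length(frames_list) - 1
  pos <- array(NA_real_, c(nrow(frames_list[[1]]), 2, n + 1))
  for (k in seq_along(frames_list)) pos[, , k] <- frames_list[[k]]
  structure(
    list(
      positions = pos, raw_positions = pos,
      closure_error_mm = rep(0, nrow(frames_list[[1]])),
      times = seq(0, 1, length.out = n + 1), plane_id = "manual"
    ),
    class = "trajectory_set"
  )
}

test_that("strain is the fractional length change of each element", {
  p0 <- rbind(c(0, 0), c(10, 0), c(0, 20))
  p1 <- rbind(c(0, 0), c(11.5, 0), c(0, 17))
  traj <- manual_traj(list(p0, p1, p0))
  el <- data.frame(i = c(1, 1), j = c(2, 3), type = c("radial", "longitudinal"))
  sf <- compute_strain(traj, el, es_frame = 2)
  expect_equal(sf$strain[, 1], c(0, 0)) # exactly zero at frame 0
  expect_equal(sf$summary$es_strain[1], 0.15) # 10 -> 11.5 mm
  expect_equal(sf$summary$es_strain[2], -0.15) # 20 -> 17 mm
})

test_that("rigid motions produce zero strain at all frames", {
  p0 <- cbind(c(0, 10, 0, 7), c(0, 0, 20, 7))
  shift <- function(d) sweep(p0, 2, d, `+`)
  rot <- function(a) p0 %*% t(matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2))
  el <- data.frame(
    i = c(1, 1, 2), j = c(2, 3, 4),
    type = c("radial", "longitudinal", "radial")
  )
  traj_t <- manual_traj(list(p0, shift(c(3, -2)), shift(c(-1, 4)), p0))
  sf_t <- compute_strain(traj_t, el, es_frame = 2)
  expect_equal(max(abs(sf_t$strain)), 0)
  for (a in c(0.1, 0.7, 2.3)) {
    traj_r <- manual_traj(list(p0, rot(a), p0))
    sf_r <- compute_strain(traj_r, el, es_frame = 2)
    expect_lt(max(abs(sf_r$strain)), 1e-12)
  }
})

test_that("degenerate elements are excluded with a warning", {
  p0 <- rbind(c(0, 0), c(0.1, 0), c(10, 0))
  traj <- manual_traj(list(p0, p0 * 1.1, p0))
  el <- data.frame(i = c(1, 1), j = c(2, 3), type = "radial")
  expect_warning(sf <- compute_strain(traj, el, es_frame = 2), "degenerate")
  expect_equal(nrow(sf$elements), 1)
})

test_that("Lagrangian strain agrees with linear strain to first order", {
  p0 <- rbind(c(0, 0), c(10, 0))
  el <- data.frame(i = 1, j = 2, type = "radial")
  for (e in c(1e-2, 1e-3)) {
    fwd <- compute_strain(
      manual_traj(list(p0, p0 * (1 + e), p0)), el,
      es_frame = 2
    )$summary$es_strain
    bwd <- compute_strain(
      manual_traj(list(p0 * (1 + e), p0, p0 * (1 + e))), el,
      es_frame = 2
    )$summary$es_strain
    expect_equal(fwd, e, tolerance = 1e-9)
    # antisymmetry only holds in the linear limit: residual is O(e^2)
    expect_lt(abs(fwd + bwd), 2 * e^2)
  }
})

test_that("tracked strain recovers the phantom ground truth", {
  spec <- example_spec() # 20 -> 15 mm endo, default shortening
  ph <- make_lv_phantom(spec)
  es_frame <- detect_es_frame(ph$sax)
  for (plane in c("2ch", "4ch")) {
    pts <- ph$lax[[plane]]$ed_points
    traj <- track_points(cbind(pts$x_mm, pts$z_mm), ph$velocity[[plane]])
    # ES positions match the analytic motion within 0.1 mm
    az <- ifelse(pts$x_mm >= 0, ph$lax[[plane]]$azimuths[1],
      ph$lax[[plane]]$azimuths[2]
    )
    es_t <- ph$times[es_frame]
    ana <- phantom_material_position(spec, pts$u, abs(pts$x_mm), az, es_t)
    err <- sqrt((abs(traj$positions[, 1, es_frame]) - ana$r_mm)^2 +
      (traj$positions[, 2, es_frame] - ana$z_mm)^2)
    expect_lt(max(err), 0.1)
    # ES radial strain within 0.02 of the closed form at every position
    sf <- compute_strain(traj, wall_elements(pts), es_frame = es_frame)
    rs <- sf$summary[sf$summary$type == "radial", ]
    truth <- phantom_truth(spec, rs$u, rs$azimuth_deg, es_t)$radial_strain
    expect_lt(max(abs(rs$es_strain - truth)), 0.02)
  }
})

test_that("global radial strain tracks global wall thickening across
           dysfunction levels", {
  wt_means <- c()
  rs_means <- c()
  for (dys in c(0, 0.3, 0.6, 1)) {
    spec <- lv_phantom_spec(
      dysfunction_model = dys, frames_per_cycle = 12,
      pixel_spacing_mm = 2.5, n_contour_vertices = 72
    )
    ph <- make_lv_phantom(spec)
    es_frame <- detect_es_frame(ph$sax)
    wt <- stack_wall_thickening(ph$sax, n_chords = 36)
    pts <- ph$lax[["2ch"]]$ed_points
    traj <- track_points(cbind(pts$x_mm, pts$z_mm), ph$velocity[["2ch"]],
      substeps = 1
    )
    sf <- compute_strain(traj, wall_elements(pts), es_frame = es_frame)
    wt_means <- c(wt_means, mean(wt$per_segment$wt_mm))
    rs_means <- c(
      rs_means,
      mean(sf$summary$es_strain[sf$summary$type == "radial"])
    )
  }
  expect_gt(stats::cor(wt_means, rs_means), 0.8)
})
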