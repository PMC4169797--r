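test_that("incompressible contraction gives the closed-form ES geometry", {
  spec <- example_spec(longitudinal_shortening_fraction = 0)
  # at the base: ES endo 15 mm, ES epi sqrt(15^2 + (30^2 - 20^2)) mm
  tr <- phantom_truth(spec, u = 1, azimuth_deg = 90, t = 0.5)
  expect_equal(tr$endo_radius_mm, 15)
  expect_equal(tr$epi_radius_mm, sqrt(725))
  expect_equal(tr$thickness_mm, sqrt(725) - 15)
  # ED thickness 10 mm at the base
  tr0 <- phantom_truth(spec, u = 1, azimuth_deg = 90, t = 0)
  expect_equal(tr0$thickness_mm, 10)
  # confirmed by numeric area integration of the generated contours:
  # annulus area pi*(epi^2 - endo^2) is conserved between ED and ES
  ph <- make_lv_phantom(spec)
  s <- ph$sax[[3]]
  a_ed <- polygon_area(s$frames[[1]]$epi) - polygon_area(s$frames[[1]]$endo)
  a_es <- polygon_area(s$frames[[11]]$epi) - polygon_area(s$frames[[11]]$endo)
  expect_equal(a_es, a_ed, tolerance = 1e-9)
})

test_that("wall cross-sectional area is conserved on every slice and frame", {
  ph <- make_lv_phantom(lv_phantom_spec(frames_per_cycle = 12))
  for (s in ph$sax) {
    areas <- vapply(s$frames, function(fr) {
      if (is.null(fr)) NA_real_ else polygon_area(fr$epi) - polygon_area(fr$endo)
    }, numeric(1))
    areas <- areas[!is.na(areas)]
    expect_lt(max(abs(areas / areas[1] - 1)), 1e-6)
  }
})

test_that("velocity field is the exact time derivative of the motion", {
  spec <- lv_phantom_spec(dysfunction_model = 0.3)
  h <- 1e-5
  for (u0 in c(0.2, 0.5, 0.9)) {
    for (t in c(0.13, 0.35, 0.72)) {
      rho0 <- phantom_endo_radius_ed(spec, u0) + 4
      p <- phantom_material_position(spec, u0, rho0, 0, c(t - h, t, t + h))
      v_fd <- c(
        (p$r_mm[3] - p$r_mm[1]) / (2 * h),
        (p$z_mm[3] - p$z_mm[1]) / (2 * h)
      ) / 10 # cm/s
      v <- phantom_velocity(spec, p$r_mm[2], p$z_mm[2], t, azimuths = c(0, 180))
      expect_equal(v$vx, v_fd[1], tolerance = 1e-6)
      expect_equal(v$vz, v_fd[2], tolerance = 1e-6)
    }
  }
})

test_that("motion is periodic and tracked trajectories close over a cycle", {
  spec <- example_spec()
  # frame-0 state equals the end-of-cycle state analytically
  p <- phantom_material_position(spec, 0.6, 25, 0, c(0, spec$cycle_duration_s))
  expect_equal(p$r_mm[1], p$r_mm[2])
  expect_equal(p$z_mm[1], p$z_mm[2])
  ph <- make_lv_phantom(spec)
  pts <- ph$lax[["2ch"]]$ed_points
  traj <- track_points(cbind(pts$x_mm, pts$z_mm), ph$velocity[["2ch"]])
  expect_lt(max(traj$closure_error_mm), 1e-3)
  # after correction, closure is exact by construction
  n <- dim(traj$positions)[3]
  expect_equal(traj$positions[, , n], traj$positions[, , 1])
})

test_that("perfusion map reproduces the specified defect under the 50% rule", {
  spec <- lv_phantom_spec(
    defect_center_azimuth_deg = 0, defect_azimuth_span_deg = 60,
    defect_apexbase_span = c(0, 0.5), defect_count_fraction = 0.4
  )
  ph <- make_lv_phantom(spec)
  mask <- quantify_defect(ph$perfusion)$mask
  az <- attr(mask, "azimuth_centers")
  ub <- attr(mask, "apexbase_centers")
  expected <- outer(ub, az, function(u, a) phantom_in_defect(spec, a, u))
  expect_equal(as.numeric(mask), as.numeric(expected))
  # counts at or above half of max are invisible to the rule
  spec2 <- lv_phantom_spec(defect_count_fraction = 0.5)
  ph2 <- make_lv_phantom(spec2)
  expect_equal(quantify_defect(ph2$perfusion)$extent_pct, 0)
})

test_that("phantom spec rejects undersampled or non-physical settings", {
  expect_error(lv_phantom_spec(frames_per_cycle = 6), "undersampled")
  expect_error(lv_phantom_spec(ed_epi_radius_mm = 19, ed_endo_radius_mm = 20))
  expect_error(lv_phantom_spec(ed_to_es_endo_fraction = 0))
  # a dysfunction multiplier pushing the endocardial scale negative
  spec <- lv_phantom_spec(dysfunction_model = 8)
  expect_error(
    phantom_truth(spec, 0.3, 0, 0.5),
    "non-physical"
  )
})

test_that("segment generator hits configured means exactly at zero SD", {
  params <- segment_sim_params(wt_sd = 0, radial_sd = 0, longitudinal_sd = 0,
    n_subjects = 3
  )
  d <- sample_segment_dataset(params)
  isch_pre <- d$wall_thickening_mm[d$class == "ischemic" & d$phase == "pre"]
  isch_post <- d$wall_thickening_mm[d$class == "ischemic" & d$phase == "post"]
  expect_true(all(isch_pre == 2.7))
  expect_true(all(isch_post == 0.65))
  adj <- d[d$class == "adjacent", ]
  expect_true(all(adj$wall_thickening_mm[adj$phase == "pre"] == 2.4))
  expect_true(all(adj$wall_thickening_mm[adj$phase == "post"] == 1.5))
  rem <- d[d$class == "remote", ]
  expect_true(all(rem$wall_thickening_mm[rem$phase == "post"] == 2.8))
})

test_that("segment generator is reproducible and consistent at large n", {
  params <- segment_sim_params(seed = 42L)
  expect_identical(sample_segment_dataset(params), sample_segment_dataset(params))
  # law of large numbers: post-ischemic mean within 3 SD / sqrt(n)
  big <- segment_sim_params(n_subjects = 1000, wt_sd = 0.5, seed = 7L)
  d <- sample_segment_dataset(big)
  v <- d$wall_thickening_mm[d$class == "ischemic" & d$phase == "post"]
  expect_lt(abs(mean(v) - 0.65), 3 * 0.5 / sqrt(length(v)))
  # class counts partition the 17 segments
  expect_error(segment_sim_params(
    segments_per_class = c(ischemic = 5, adjacent = 5, remote = 5)
  ))
})

test_that("dysfunction multiplier can be solved for a target thickening", {
  spec <- lv_phantom_spec()
  for (target in c(0.65, 1.5, 2.8)) {
    m <- dysfunction_for_thickening(spec, u = 0.5, target_wt_mm = target)
    s2 <- lv_phantom_spec(dysfunction_model = function(az, u) m)
    wt <- phantom_truth(s2, 0.5, 0, 0.5)$thickness_mm -
      phantom_truth(s2, 0.5, 0, 0)$thickness_mm
    expect_equal(wt, target, tolerance = 1e-8)
  }
})
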