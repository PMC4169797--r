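test_that("centerline thickness is exact for concentric circles", {
  for (n_chords in c(64, 80)) {
    p <- compute_thickness(circle_contour(20), circle_contour(30), n_chords)
    expect_lt(max(abs(p$thickness_mm - 10)) / 10, 0.001)
    expect_length(p$thickness_mm, n_chords)
  }
})

test_that("offset endocardium shifts thickness as the geometry predicts", {
  endo <- circle_contour(20, center = c(2, 0)) # offset toward azimuth 0
  p <- compute_thickness(endo, circle_contour(30), 80)
  expect_equal(p$thickness_mm[p$azimuth_deg == 0], 8, tolerance = 0.02)
  expect_equal(p$thickness_mm[p$azimuth_deg == 180], 12, tolerance = 0.02)
})

test_that("invalid contour geometry is rejected", {
  # endo polygon partially outside the epi -> containment error
  expect_error(
    compute_thickness(circle_contour(20, center = c(15, 0)), circle_contour(30)),
    "containment"
  )
  # bow-tie self intersection
  bowtie <- rbind(c(-1, -1), c(1, 1), c(1, -1), c(-1, 1)) * 5
  expect_error(
    compute_thickness(bowtie, circle_contour(30)),
    "self-intersecting"
  )
})

test_that("wall thickening and fractional thickening follow the definitions", {
  ed <- compute_thickness(circle_contour(15), circle_contour(25), 80,
    apexbase = 0.5
  )
  es <- compute_thickness(circle_contour(14), circle_contour(26), 80,
    apexbase = 0.5
  )
  wt <- compute_wall_thickening(ed, es)
  expect_equal(mean(wt$wt_mm), 2, tolerance = 1e-3)
  expect_equal(mean(wt$fwt), 0.2, tolerance = 1e-3)
  # no thickening
  wt0 <- compute_wall_thickening(ed, ed)
  expect_true(all(wt0$wt_mm == 0) && all(wt0$fwt == 0))
  # FWT is invariant under uniform spatial rescaling (dimensionless)
  ed2 <- compute_thickness(circle_contour(15 * 3), circle_contour(25 * 3), 80)
  es2 <- compute_thickness(circle_contour(14 * 3), circle_contour(26 * 3), 80)
  wt2 <- compute_wall_thickening(ed2, es2)
  expect_equal(mean(wt2$fwt), mean(wt$fwt), tolerance = 1e-6)
  # mismatched chord grids
  es3 <- compute_thickness(circle_contour(14), circle_contour(26), 64)
  expect_error(compute_wall_thickening(ed, es3), "chord grids")
})

test_that("incompressible annulus thickening matches the closed form", {
  # 20 -> 15 mm endo with 30 mm epi: WT = (sqrt(725) - 15) - 10 mm
  ed <- compute_thickness(circle_contour(20), circle_contour(30), 80)
  es <- compute_thickness(circle_contour(15), circle_contour(sqrt(725)), 80)
  wt <- compute_wall_thickening(ed, es)
  expect_equal(mean(wt$wt_mm), sqrt(725) - 25, tolerance = 0.01)
})

test_that("basal-slice rule keeps the contiguous range from the first full ring", {
  expect_equal(select_basal_slices(c(FALSE, TRUE, TRUE, TRUE)), 2:4)
  expect_equal(select_basal_slices(rep(TRUE, 5)), 1:5)
  expect_error(select_basal_slices(rep(FALSE, 4)), "empty selection")
})

test_that("single-slice volume arithmetic and EF", {
  # endo area 10 cm^2 at ED, 5 cm^2 at ES, slice 0.8 cm
  r_ed <- sqrt(1000 / pi)
  r_es <- sqrt(500 / pi)
  n <- 720 # fine polygon so the discretized area is within rounding
  sax <- list(list(
    plane_id = "sax01", z_mm = 4, apexbase = 0.5,
    frames = list(
      list(endo = circle_contour(r_ed, n), epi = circle_contour(r_ed + 8, n)),
      list(endo = circle_contour(r_es, n), epi = circle_contour(r_es + 10, n))
    ),
    full_circumference = c(TRUE, TRUE)
  ))
  gf <- compute_volumes_mass(sax, slice_thickness_mm = 8, hr_bpm = 60)
  expect_equal(gf$edv_ml, 8, tolerance = 1e-3)
  expect_equal(gf$esv_ml, 4, tolerance = 1e-3)
  expect_equal(gf$sv_ml, 4, tolerance = 1e-3)
  expect_equal(gf$ef_percent, 50, tolerance = 0.05)
  expect_equal(gf$co_l_min, 4 * 60 / 1000, tolerance = 1e-3)
})

test_that("stack volume matches the closed-form half-ellipsoid within 2%", {
  spec <- lv_phantom_spec(longitudinal_shortening_fraction = 0)
  ph <- make_lv_phantom(spec)
  gf <- compute_volumes_mass(ph$sax, spec$slice_thickness_mm)
  v_analytic <- 2 / 3 * pi * spec$ed_endo_radius_mm^2 *
    spec$long_axis_length_mm / 1000
  expect_lt(abs(gf$edv_ml / v_analytic - 1), 0.02)
  # ES cavity: endo radii scaled by f everywhere
  v_es <- v_analytic * spec$ed_to_es_endo_fraction^2
  expect_lt(abs(gf$esv_ml / v_es - 1), 0.02)
  # mass = wall volume: pi * (R_epi^2 - R_endo^2) * L
  m_analytic <- pi * (spec$ed_epi_radius_mm^2 - spec$ed_endo_radius_mm^2) *
    spec$long_axis_length_mm / 1000
  expect_lt(abs(gf$lv_mass_ml / m_analytic - 1), 0.02)
})

test_that("stack thickening on a dysfunctional phantom matches ground truth", {
  spec <- lv_phantom_spec(dysfunction_model = 0.2, frames_per_cycle = 12)
  ph <- make_lv_phantom(spec)
  res <- stack_wall_thickening(ph$sax, n_chords = 48)
  es_t <- ph$times[res$es_frame]
  az <- (seq_len(48) - 1) * 360 / 48
  # per-chord oracle: closed-form ED and ES thickness at the chord azimuths,
  # away from the defect edges where the contour radius is discontinuous and
  # a finite-vertex polygon cannot follow the jump
  edges <- spec$defect_center_azimuth_deg +
    c(-1, 1) * spec$defect_azimuth_span_deg / 2
  edge_dist <- pmin(
    abs((az - edges[1] + 180) %% 360 - 180),
    abs((az - edges[2] + 180) %% 360 - 180)
  )
  interior <- edge_dist > 360 / spec$n_contour_vertices
  for (i in res$included_slices) {
    s <- ph$sax[[i]]
    beta_es <- (1 - cos(2 * pi * es_t)) / 2
    u_es <- s$z_mm / ((1 - spec$longitudinal_shortening_fraction * beta_es) *
      spec$long_axis_length_mm) # material slice at the fixed plane at ES
    prof_ed <- compute_thickness(
      s$frames[[1]]$endo, s$frames[[1]]$epi, 48, validate = FALSE
    )
    prof_es <- compute_thickness(
      s$frames[[res$es_frame]]$endo, s$frames[[res$es_frame]]$epi, 48,
      validate = FALSE
    )
    wt_meas <- prof_es$thickness_mm - prof_ed$thickness_mm
    wt_true <- phantom_truth(spec, u_es, az, es_t)$thickness_mm -
      phantom_truth(spec, s$apexbase, az, 0)$thickness_mm
    expect_lt(max(abs(wt_meas[interior] - wt_true[interior])), 0.05)
  }
  # segment means stay close to the same-chord oracle despite edge mixing
  rows <- lapply(res$included_slices, function(i) {
    s <- ph$sax[[i]]
    beta_es <- (1 - cos(2 * pi * es_t)) / 2
    u_es <- s$z_mm / ((1 - spec$longitudinal_shortening_fraction * beta_es) *
      spec$long_axis_length_mm)
    data.frame(
      segment = assign_segment(s$apexbase, az),
      wt = phantom_truth(spec, u_es, az, es_t)$thickness_mm -
        phantom_truth(spec, s$apexbase, az, 0)$thickness_mm
    )
  })
  truth <- do.call(rbind, rows)
  truth_seg <- tapply(truth$wt, truth$segment, mean)
  expect_equal(
    res$per_segment$wt_mm,
    as.numeric(truth_seg[as.character(res$per_segment$segment)]),
    tolerance = 0.1
  )
})
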