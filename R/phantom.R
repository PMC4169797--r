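#' Analytic deforming left-ventricle phantom
#'
#' The phantom models the LV as a truncated prolate half-ellipsoid treated as
#' a stack of circular annuli. The endocardial surface at end diastole (ED)
#' has radius `r_endo(u) = R_endo * sqrt(2u - u^2)` at normalized apex-to-base
#' position `u` (0 = apex tip, 1 = base/equator), and the wall keeps a
#' constant cross-sectional area per slice: `r_epi(u)^2 - r_endo(u)^2 =
#' R_epi^2 - R_endo^2` at all positions and all times (incompressible wall in
#' the imaging plane). Systole scales the endocardial radius by a smooth
#' sinusoidal factor and shortens the long axis affinely toward the apex, so
#' the motion, the in-plane velocity field and the radial/longitudinal strain
#' are all available in closed form.
#'
#' @name phantom
NULL

#' Phantom specification
#'
#' @param ed_endo_radius_mm,ed_epi_radius_mm ED endo/epicardial radii at the
#'   base (epi must exceed endo).
#' @param long_axis_length_mm apex-to-base length at ED.
#' @param ed_to_es_endo_fraction endocardial radius scale at end systole,
#'   in (0, 1].
#' @param longitudinal_shortening_fraction fraction of the long axis lost at
#'   end systole, in `[0, 1)`.
#' @param frames_per_cycle number of velocity/contour frames per cardiac
#'   cycle (>= 8).
#' @param cycle_duration_s cardiac cycle length in seconds.
#' @param pixel_spacing_mm raster spacing of the velocity fields.
#' @param slice_thickness_mm short-axis slice thickness/spacing.
#' @param n_contour_vertices vertices per short-axis contour.
#' @param defect_center_azimuth_deg,defect_azimuth_span_deg,defect_apexbase_span
#'   geometry of the perfusion defect: azimuthal center and span (degrees) and
#'   the apex-to-base interval `[lo, hi)` it covers. A zero span disables the
#'   defect.
#' @param defect_count_fraction perfusion counts inside the defect relative
#'   to the map maximum, in `[0, 1)`. Values of 0.5 and above make the defect
#'   invisible to the 50%-of-maximum rule.
#' @param infarct_transmurality,infarct_azimuth_span_deg,infarct_apexbase_span
#'   late-enhancement map: transmural extent (0..1) over a region nested
#'   inside the defect (same azimuthal center).
#' @param dysfunction_model multiplier applied to the prescribed radial
#'   contraction inside the defect (1 = fully functional), or a function of
#'   `(azimuth_deg, apexbase)` returning a multiplier anywhere.
#' @param velocity_noise_sd_cm_s additive Gaussian noise on the velocity
#'   rasters (cm/s); default off.
#' @param venc_cm_s velocity-encoding limit recorded in the output metadata.
#' @param seed integer seed used for velocity noise.
#' @return object of class `phantom_spec`.
#' @export
lv_phantom_spec <- function(ed_endo_radius_mm = 20,
                            ed_epi_radius_mm = 28,
                            long_axis_length_mm = 80,
                            ed_to_es_endo_fraction = 0.8,
                            longitudinal_shortening_fraction = 0.1,
                            frames_per_cycle = 20,
                            cycle_duration_s = 1.0,
                            pixel_spacing_mm = 1.6,
                            slice_thickness_mm = 8,
                            n_contour_vertices = 120,
                            defect_center_azimuth_deg = 0,
                            defect_azimuth_span_deg = 120,
                            defect_apexbase_span = c(0, 0.6),
                            defect_count_fraction = 0.3,
                            infarct_transmurality = 0.9,
                            infarct_azimuth_span_deg = 120,
                            infarct_apexbase_span = c(0, 0.5),
                            dysfunction_model = 1,
                            velocity_noise_sd_cm_s = 0,
                            venc_cm_s = 20,
                            seed = 1L) {
  stopifnot(
    ed_endo_radius_mm > 0, ed_epi_radius_mm > ed_endo_radius_mm,
    long_axis_length_mm > 0,
    ed_to_es_endo_fraction > 0, ed_to_es_endo_fraction <= 1,
    longitudinal_shortening_fraction >= 0, longitudinal_shortening_fraction < 1,
    cycle_duration_s > 0, pixel_spacing_mm > 0, slice_thickness_mm > 0,
    defect_count_fraction >= 0, defect_count_fraction < 1,
    length(defect_apexbase_span) == 2,
    defect_apexbase_span[1] <= defect_apexbase_span[2],
    infarct_transmurality >= 0, infarct_transmurality <= 1,
    velocity_noise_sd_cm_s >= 0
  )
  if (frames_per_cycle < 8) {
    stop("frames_per_cycle must be >= 8 (tracking would be undersampled)",
      call. = FALSE
    )
  }
  # the ES epicardial radius must be real: f^2 * r_endo^2 + (R_epi^2 -
  # R_endo^2) >= 0 always holds for R_epi > R_endo, but a custom dysfunction
  # multiplier > 1/(1-f) could push the scale negative
  spec <- list(
    ed_endo_radius_mm = ed_endo_radius_mm,
    ed_epi_radius_mm = ed_epi_radius_mm,
    long_axis_length_mm = long_axis_length_mm,
    ed_to_es_endo_fraction = ed_to_es_endo_fraction,
    longitudinal_shortening_fraction = longitudinal_shortening_fraction,
    frames_per_cycle = as.integer(frames_per_cycle),
    cycle_duration_s = cycle_duration_s,
    pixel_spacing_mm = pixel_spacing_mm,
    slice_thickness_mm = slice_thickness_mm,
    n_contour_vertices = as.integer(n_contour_vertices),
    defect_center_azimuth_deg = defect_center_azimuth_deg,
    defect_azimuth_span_deg = defect_azimuth_span_deg,
    defect_apexbase_span = defect_apexbase_span,
    defect_count_fraction = defect_count_fraction,
    infarct_transmurality = infarct_transmurality,
    infarct_azimuth_span_deg = infarct_azimuth_span_deg,
    infarct_apexbase_span = infarct_apexbase_span,
    dysfunction_model = dysfunction_model,
    velocity_noise_sd_cm_s = velocity_noise_sd_cm_s,
    venc_cm_s = venc_cm_s,
    seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  spec
}

# ---- closed-form building blocks --------------------------------------------

# smooth contraction time course: 0 at t = 0, 1 at mid cycle, 0 at t = T
.ph_beta <- function(t, T) (1 - cos(2 * pi * t / T)) / 2
.ph_beta_dot <- function(t, T) (pi / T) * sin(2 * pi * t / T)

#' ED endocardial radius profile of the phantom
#' @param spec a `phantom_spec`.
#' @param u apex-to-base fraction(s), clamped to `[0, 1]`.
#' @export
phantom_endo_radius_ed <- function(spec, u) {
  u <- pmin(pmax(u, 0), 1)
  spec$ed_endo_radius_mm * sqrt(pmax(2 * u - u^2, 0))
}

# constant wall cross-section (mm^2 / pi) per slice
.ph_wall_const <- function(spec) {
  spec$ed_epi_radius_mm^2 - spec$ed_endo_radius_mm^2
}

# shortest angular distance (degrees)
.ang_dist <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Polar membership of the phantom perfusion defect
#' @inheritParams phantom_endo_radius_ed
#' @param azimuth_deg,u polar coordinates (vectorized).
#' @return logical vector.
#' @export
phantom_in_defect <- function(spec, azimuth_deg, u) {
  if (spec$defect_azimuth_span_deg <= 0) {
    return(rep(FALSE, max(length(azimuth_deg), length(u))))
  }
  n <- max(length(azimuth_deg), length(u))
  az <- rep_len(azimuth_deg, n)
  u <- rep_len(u, n)
  .ang_dist(az, spec$defect_center_azimuth_deg) <
    spec$defect_azimuth_span_deg / 2 &
    u >= spec$defect_apexbase_span[1] & u < spec$defect_apexbase_span[2]
}

.ph_in_infarct <- function(spec, azimuth_deg, u) {
  if (spec$infarct_azimuth_span_deg <= 0) {
    return(rep(FALSE, max(length(azimuth_deg), length(u))))
  }
  n <- max(length(azimuth_deg), length(u))
  az <- rep_len(azimuth_deg, n)
  u <- rep_len(u, n)
  .ang_dist(az, spec$defect_center_azimuth_deg) <
    spec$infarct_azimuth_span_deg / 2 &
    u >= spec$infarct_apexbase_span[1] & u < spec$infarct_apexbase_span[2]
}

#' Local motion multiplier (dysfunction model)
#'
#' 1 means the full prescribed contraction; values below 1 reduce the radial
#' excursion (hypokinesia), 0 freezes the wall (akinesia).
#' @inheritParams phantom_in_defect
#' @export
phantom_multiplier <- function(spec, azimuth_deg, u) {
  if (is.function(spec$dysfunction_model)) {
    return(spec$dysfunction_model(azimuth_deg, u))
  }
  ifelse(phantom_in_defect(spec, azimuth_deg, u),
    spec$dysfunction_model, 1
  )
}

# endocardial scale s(t) and its time derivative for multiplier m
.ph_scale <- function(spec, m, t) {
  1 - m * (1 - spec$ed_to_es_endo_fraction) * .ph_beta(t, spec$cycle_duration_s)
}
.ph_scale_dot <- function(spec, m, t) {
  -m * (1 - spec$ed_to_es_endo_fraction) *
    .ph_beta_dot(t, spec$cycle_duration_s)
}
.ph_lambda <- function(spec, t) {
  spec$longitudinal_shortening_fraction * .ph_beta(t, spec$cycle_duration_s)
}
.ph_lambda_dot <- function(spec, t) {
  spec$longitudinal_shortening_fraction *
    .ph_beta_dot(t, spec$cycle_duration_s)
}

#' Closed-form wall thickness, radial and longitudinal strain
#'
#' Radial strain is the fractional change of the endo-to-epi wall thickness
#' relative to ED; longitudinal strain is `-lambda(t)` (affine long-axis
#' shortening, uniform over the wall).
#'
#' @inheritParams phantom_in_defect
#' @param t time(s) in seconds (vectorized with `u`/`azimuth_deg`).
#' @return data.frame with `u`, `azimuth_deg`, `t`, `endo_radius_mm`,
#'   `epi_radius_mm`, `thickness_mm`, `radial_strain`, `longitudinal_strain`.
#' @export
phantom_truth <- function(spec, u, azimuth_deg, t) {
  n <- max(length(u), length(azimuth_deg), length(t))
  u <- rep_len(u, n)
  az <- rep_len(azimuth_deg, n)
  t <- rep_len(t, n)
  re0 <- phantom_endo_radius_ed(spec, u)
  C <- .ph_wall_const(spec)
  m <- phantom_multiplier(spec, az, u)
  s <- .ph_scale(spec, m, t)
  if (any(s <= 0)) {
    stop("non-physical contraction: endocardial scale <= 0", call. = FALSE)
  }
  endo <- s * re0
  disc <- endo^2 + C
  if (any(disc < 0)) {
    stop("non-physical geometry: negative discriminant for the ES ",
      "epicardial radius",
      call. = FALSE
    )
  }
  epi <- sqrt(disc)
  th0 <- sqrt(re0^2 + C) - re0
  th <- epi - endo
  data.frame(
    u = u, azimuth_deg = az, t = t,
    endo_radius_mm = endo, epi_radius_mm = epi, thickness_mm = th,
    radial_strain = th / th0 - 1,
    longitudinal_strain = -.ph_lambda(spec, t)
  )
}

#' Analytic material trajectory of a wall point
#'
#' @inheritParams phantom_in_defect
#' @param u0 material apex-to-base fraction at ED.
#' @param rho0_mm material radius at ED (between the ED endo and epi radii).
#' @param t times (s).
#' @return data.frame with `t`, `r_mm` (distance from the long axis) and
#'   `z_mm` (height above the apex tip).
#' @export
phantom_material_position <- function(spec, u0, rho0_mm, azimuth_deg, t) {
  re0 <- phantom_endo_radius_ed(spec, u0)
  m <- phantom_multiplier(spec, azimuth_deg, u0)
  s <- .ph_scale(spec, m, t)
  r <- sqrt(pmax(rho0_mm^2 + (s^2 - 1) * re0^2, 0))
  z <- u0 * spec$long_axis_length_mm * (1 - .ph_lambda(spec, t))
  data.frame(t = t, r_mm = r, z_mm = z)
}

#' Eulerian in-plane velocity of the phantom on a long-axis plane
#'
#' Long-axis planes are meridional cuts: in-plane coordinates are the signed
#' distance `x` from the long axis (positive side at `azimuths[1]`, negative
#' at `azimuths[2]`) and the height `z` above the apex tip. The field is the
#' exact time derivative of the prescribed motion, extended smoothly beyond
#' the wall so interpolation near the boundaries stays consistent.
#'
#' @inheritParams phantom_in_defect
#' @param x_mm,z_mm plane coordinates (vectorized, equal length).
#' @param t scalar time (s).
#' @param azimuths length-2 azimuths of the two plane halves (degrees).
#' @return list of numeric vectors `vx`, `vz` in cm/s.
#' @export
phantom_velocity <- function(spec, x_mm, z_mm, t, azimuths = c(0, 180)) {
  lam <- .ph_lambda(spec, t)
  lam_dot <- .ph_lambda_dot(spec, t)
  z0 <- z_mm / (1 - lam)
  u0 <- pmin(pmax(z0 / spec$long_axis_length_mm, 0), 1)
  re0 <- phantom_endo_radius_ed(spec, u0)
  az <- ifelse(x_mm >= 0, azimuths[1], azimuths[2])
  m <- phantom_multiplier(spec, az, u0)
  s <- .ph_scale(spec, m, t)
  s_dot <- .ph_scale_dot(spec, m, t)
  # v_r = s s' re0^2 / r from r^2 = rho0^2 + (s^2 - 1) re0^2; regularize the
  # removable blow-up near the long axis (outside the wall) linearly
  x_eps <- spec$pixel_spacing_mm / 2
  vx <- ifelse(abs(x_mm) >= x_eps,
    s * s_dot * re0^2 / x_mm,
    s * s_dot * re0^2 * x_mm / x_eps^2
  )
  vz <- -z0 * lam_dot
  list(vx = vx / 10, vz = vz / 10) # mm/s -> cm/s
}

# ---- phantom assembly -------------------------------------------------------

.ph_times <- function(spec) {
  (seq_len(spec$frames_per_cycle) - 1) *
    spec$cycle_duration_s / spec$frames_per_cycle
}

# short-axis contour on the fixed plane at height z_mm, time t; NULL when the
# plane lies above the (moving) base
.ph_sax_contour <- function(spec, z_mm, t) {
  lam <- .ph_lambda(spec, t)
  z0 <- z_mm / (1 - lam)
  if (z0 > spec$long_axis_length_mm || z0 < 0) {
    return(NULL)
  }
  u0 <- z0 / spec$long_axis_length_mm
  nv <- spec$n_contour_vertices
  az <- (seq_len(nv) - 1) * 360 / nv
  tr <- phantom_truth(spec, u0, az, t)
  rad <- az * pi / 180
  list(
    endo = cbind(
      x = tr$endo_radius_mm * cos(rad),
      y = tr$endo_radius_mm * sin(rad)
    ),
    epi = cbind(
      x = tr$epi_radius_mm * cos(rad),
      y = tr$epi_radius_mm * sin(rad)
    ),
    apexbase = u0
  )
}

# ED boundary chains for one long-axis plane: endo and epi points on both
# sides, ordered apex -> base, on a material u grid
.ph_lax_points <- function(spec, azimuths, n_per_chain = 16,
                           u_range = c(0.08, 0.95)) {
  u <- seq(u_range[1], u_range[2], length.out = n_per_chain)
  re0 <- phantom_endo_radius_ed(spec, u)
  rp0 <- sqrt(re0^2 + .ph_wall_const(spec))
  z <- u * spec$long_axis_length_mm
  side <- function(sgn, az) {
    rbind(
      data.frame(
        role = "endo", side = az, u = u, x_mm = sgn * re0, z_mm = z
      ),
      data.frame(
        role = "epi", side = az, u = u, x_mm = sgn * rp0, z_mm = z
      )
    )
  }
  rbind(side(1, azimuths[1]), side(-1, azimuths[2]))
}

# sampled velocity raster for one long-axis plane
.ph_velocity_raster <- function(spec, azimuths, plane_id) {
  margin <- 4
  half <- spec$ed_epi_radius_mm + margin
  x <- seq(-half, half, by = spec$pixel_spacing_mm)
  z <- seq(-margin, spec$long_axis_length_mm + margin,
    by = spec$pixel_spacing_mm
  )
  times <- .ph_times(spec)
  g <- expand.grid(x = x, z = z)
  vx <- array(0, c(length(x), length(z), length(times)))
  vz <- vx
  for (k in seq_along(times)) {
    v <- phantom_velocity(spec, g$x, g$z, times[k], azimuths)
    vx[, , k] <- v$vx
    vz[, , k] <- v$vz
  }
  if (spec$velocity_noise_sd_cm_s > 0) {
    vx <- vx + stats::rnorm(length(vx), 0, spec$velocity_noise_sd_cm_s)
    vz <- vz + stats::rnorm(length(vz), 0, spec$velocity_noise_sd_cm_s)
  }
  velocity_field(vx, vz,
    x_mm = x, z_mm = z, times = times,
    cycle_duration_s = spec$cycle_duration_s,
    venc_cm_s = spec$venc_cm_s, plane_id = plane_id, azimuths = azimuths
  )
}

#' Generate all synthetic inputs from a phantom specification
#'
#' Produces the short-axis contour stack, long-axis ED boundary chains,
#' in-plane velocity rasters for the 2/3/4-chamber planes, the perfusion and
#' late-enhancement polar maps, and the closed-form ground-truth record.
#'
#' @param spec a [lv_phantom_spec()].
#' @return object of class `lv_phantom`: list with elements `spec`, `times`,
#'   `sax` (slices base-to-apex, each with `z_mm`, `apexbase`, per-frame
#'   `endo`/`epi` contours and a `full_circumference` flag per frame), `lax`
#'   (per plane: ED point chains), `velocity` (per plane:
#'   [velocity_field()]), `perfusion` and `lge` (polar maps), and `truth`
#'   (data.frame of analytic strain/thickness on a polar grid per frame).
#' @export
make_lv_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  times <- .ph_times(spec)
  L <- spec$long_axis_length_mm

  # fixed short-axis planes, base -> apex, centered in 8 mm slabs
  n_slices <- floor(L / spec$slice_thickness_mm)
  z_planes <- L - (seq_len(n_slices) - 0.5) * spec$slice_thickness_mm
  sax <- lapply(seq_len(n_slices), function(i) {
    frames <- lapply(times, function(t) .ph_sax_contour(spec, z_planes[i], t))
    list(
      plane_id = sprintf("sax%02d", i),
      z_mm = z_planes[i],
      apexbase = z_planes[i] / L,
      frames = frames,
      full_circumference = !vapply(frames, is.null, logical(1))
    )
  })

  planes <- lax_plane_azimuths()
  lax <- lapply(names(planes), function(p) {
    list(
      plane_id = p, azimuths = planes[[p]],
      ed_points = .ph_lax_points(spec, planes[[p]])
    )
  })
  names(lax) <- names(planes)
  velocity <- lapply(names(planes), function(p) {
    .ph_velocity_raster(spec, planes[[p]], p)
  })
  names(velocity) <- names(planes)

  perfusion <- polar_map_from_fn(
    function(u, az) {
      ifelse(phantom_in_defect(spec, az, u), spec$defect_count_fraction, 1)
    },
    label = "perfusion_counts"
  )
  lge <- polar_map_from_fn(
    function(u, az) {
      ifelse(.ph_in_infarct(spec, az, u), spec$infarct_transmurality, 0)
    },
    label = "infarct_transmurality"
  )

  u_grid <- (seq_len(20) - 0.5) / 20
  az_grid <- (seq_len(36) - 0.5) * 10
  grid <- expand.grid(u = u_grid, azimuth = az_grid)
  truth <- do.call(rbind, lapply(seq_along(times), function(k) {
    tr <- phantom_truth(spec, grid$u, grid$azimuth, times[k])
    tr$frame <- k
    tr
  }))

  structure(
    list(
      spec = spec, times = times, sax = sax, lax = lax,
      velocity = velocity, perfusion = perfusion, lge = lge, truth = truth
    ),
    class = "lv_phantom"
  )
}

#' @export
print.lv_phantom <- function(x, ...) {
  cat(sprintf(
    "lv_phantom: %d short-axis slices, %d long-axis planes, %d frames\n",
    length(x$sax), length(x$lax), length(x$times)
  ))
  invisible(x)
}

# ---- segment-level statistical generator ------------------------------------

# segment ids ordered from the anterior/anteroapical (LAD) territory outward;
# the first k ischemic segments are taken from the front of this list
.SEG_PRIORITY <- c(13, 14, 17, 7, 8, 1, 2, 15, 16, 9, 12, 3, 6, 10, 11, 4, 5)

#' Parameters for the segment-level statistical generator
#'
#' Defaults encode the reported pre/post class means of the porcine
#' ischemia-reperfusion experiment the phantom emulates: wall thickening
#' 2.7 -> 0.65 mm (ischemic), 2.4 -> 1.5 mm (adjacent), 2.4 -> 2.8 mm
#' (remote). Per-segment standard deviations are not reported; defaults are
#' 0.5 mm for thickening and 0.05 for strain.
#'
#' @param wt_mean,radial_mean,longitudinal_mean named lists with entries
#'   `ischemic`, `adjacent`, `remote`, each a length-2 vector `c(pre, post)`.
#' @param wt_sd,radial_sd,longitudinal_sd standard deviations (>= 0).
#' @param n_subjects number of subjects.
#' @param segments_per_class named integer vector (`ischemic`, `adjacent`,
#'   `remote`) summing to 17.
#' @param seed integer seed.
#' @return object of class `segment_sim_params`.
#' @export
segment_sim_params <- function(
    wt_mean = list(
      ischemic = c(pre = 2.7, post = 0.65),
      adjacent = c(pre = 2.4, post = 1.5),
      remote = c(pre = 2.4, post = 2.8)
    ),
    radial_mean = list(
      ischemic = c(pre = 0.17, post = 0.03),
      adjacent = c(pre = 0.17, post = 0.10),
      remote = c(pre = 0.17, post = 0.20)
    ),
    longitudinal_mean = list(
      ischemic = c(pre = -0.09, post = -0.02),
      adjacent = c(pre = -0.09, post = -0.055),
      remote = c(pre = -0.09, post = -0.09)
    ),
    wt_sd = 0.5, radial_sd = 0.05, longitudinal_sd = 0.05,
    n_subjects = 10,
    segments_per_class = c(ischemic = 5, adjacent = 5, remote = 7),
    seed = 1L) {
  stopifnot(
    wt_sd >= 0, radial_sd >= 0, longitudinal_sd >= 0,
    n_subjects >= 1,
    sum(segments_per_class) == 17,
    all(segments_per_class >= 0),
    setequal(names(segments_per_class), c("ischemic", "adjacent", "remote"))
  )
  for (m in list(wt_mean, radial_mean, longitudinal_mean)) {
    stopifnot(setequal(names(m), c("ischemic", "adjacent", "remote")))
  }
  structure(
    list(
      wt_mean = wt_mean, radial_mean = radial_mean,
      longitudinal_mean = longitudinal_mean,
      wt_sd = wt_sd, radial_sd = radial_sd, longitudinal_sd = longitudinal_sd,
      n_subjects = as.integer(n_subjects),
      segments_per_class = segments_per_class,
      seed = as.integer(seed)
    ),
    class = "segment_sim_params"
  )
}

#' Class label of each AHA segment under a class partition
#'
#' Ischemic segments are taken from the anterior (LAD-territory) end of a
#' fixed priority order, adjacent segments next, the rest remote.
#'
#' @param segments_per_class named counts summing to 17.
#' @return character vector of 17 labels indexed by segment id.
#' @export
segment_class_labels <- function(segments_per_class) {
  stopifnot(sum(segments_per_class) == 17)
  k1 <- segments_per_class[["ischemic"]]
  k2 <- segments_per_class[["adjacent"]]
  lab <- character(17)
  lab[.SEG_PRIORITY[seq_len(k1)]] <- "ischemic"
  if (k2 > 0) lab[.SEG_PRIORITY[k1 + seq_len(k2)]] <- "adjacent"
  lab[lab == ""] <- "remote"
  lab
}

#' Draw a segment-level pre/post dataset
#'
#' Values are drawn independently per subject x segment from the per-class
#' normal distributions in `params`; the class label of every segment is
#' recorded as ground truth.
#'
#' @param params a [segment_sim_params()].
#' @param labels optional character vector of 17 class labels overriding the
#'   priority-based assignment (e.g. labels measured from a perfusion map);
#'   must agree with `params$segments_per_class`.
#' @return data.frame (class `segment_table`) with columns `subject`,
#'   `segment`, `class`, `phase` (pre/post), `wall_thickening_mm`,
#'   `radial_strain`, `longitudinal_strain`.
#' @export
sample_segment_dataset <- function(params, labels = NULL) {
  stopifnot(inherits(params, "segment_sim_params"))
  set.seed(params$seed)
  if (is.null(labels)) {
    labels <- segment_class_labels(params$segments_per_class)
  } else {
    stopifnot(
      length(labels) == 17,
      all(table(factor(labels, names(params$segments_per_class))) ==
        params$segments_per_class)
    )
  }
  grid <- expand.grid(
    subject = seq_len(params$n_subjects), segment = 1:17,
    phase = c("pre", "post"), stringsAsFactors = FALSE
  )
  grid$class <- labels[grid$segment]
  draw <- function(means, sd) {
    mu <- mapply(function(cl, ph) means[[cl]][[ph]], grid$class, grid$phase)
    stats::rnorm(nrow(grid), mu, sd)
  }
  grid$wall_thickening_mm <- draw(params$wt_mean, params$wt_sd)
  grid$radial_strain <- draw(params$radial_mean, params$radial_sd)
  grid$longitudinal_strain <- draw(
    params$longitudinal_mean,
    params$longitudinal_sd
  )
  out <- grid[order(grid$phase, grid$subject, grid$segment), ]
  rownames(out) <- NULL
  class(out) <- c("segment_table", "data.frame")
  out
}

#' Dysfunction multiplier reproducing a target end-systolic wall thickening
#'
#' Solves for the radial-contraction multiplier that makes the closed-form
#' wall thickening at position `u` equal `target_wt_mm`, so phantom regions
#' can be configured to hit prescribed class means.
#'
#' @inheritParams phantom_endo_radius_ed
#' @param u apex-to-base position at which to match.
#' @param target_wt_mm desired ES minus ED thickness (mm).
#' @return scalar multiplier (possibly negative for paradoxical thinning).
#' @export
dysfunction_for_thickening <- function(spec, u, target_wt_mm) {
  re0 <- phantom_endo_radius_ed(spec, u)
  C <- .ph_wall_const(spec)
  th0 <- sqrt(re0^2 + C) - re0
  f <- function(m) {
    s <- 1 - m * (1 - spec$ed_to_es_endo_fraction)
    (sqrt((s * re0)^2 + C) - s * re0) - th0 - target_wt_mm
  }
  stats::uniroot(f, c(-2, 1 / (1 - spec$ed_to_es_endo_fraction) - 1e-6),
    tol = 1e-10
  )$root
}
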