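#' Velocity-encoded boundary tracking and Lagrangian strain
#'
#' Material points segmented at end diastole are advanced through the
#' velocity-encoded image sequence by fourth-order Runge-Kutta integration
#' with bilinear spatial and linear temporal interpolation of the velocity.
#' Because measured velocities never integrate to an exactly closed loop over
#' one cardiac cycle, the residual drift of each trajectory is redistributed
#' linearly over the frames (cycle-closure correction), after which every
#' trajectory is periodic by construction. Strain is the fractional length
#' change of point pairs: endo-to-epi pairs along the wall normal give radial
#' strain, neighboring pairs along the wall give longitudinal strain.
#'
#' @name ve_strain
NULL

#' Construct a velocity field
#'
#' @param vx,vz numeric arrays `[nx, nz, n_frames]` of in-plane velocity
#'   components (cm/s): `vx` across the long axis, `vz` along it.
#' @param x_mm,z_mm pixel-center coordinates (equally spaced, mm).
#' @param times frame times (s), starting at 0, covering one cycle.
#' @param cycle_duration_s cycle length (s); the field is periodic with this
#'   period.
#' @param venc_cm_s velocity-encoding limit; sampled speeds above it trigger
#'   an aliasing warning during tracking.
#' @param plane_id,azimuths plane metadata (see [lax_plane_azimuths()]).
#' @return object of class `velocity_field`.
#' @export
velocity_field <- function(vx, vz, x_mm, z_mm, times, cycle_duration_s,
                           venc_cm_s = 20, plane_id = "plane",
                           azimuths = c(0, 180)) {
  stopifnot(
    length(dim(vx)) == 3, identical(dim(vx), dim(vz)),
    dim(vx)[1] == length(x_mm), dim(vx)[2] == length(z_mm),
    dim(vx)[3] == length(times),
    times[1] == 0, cycle_duration_s > max(times)
  )
  structure(
    list(
      vx = vx, vz = vz, x_mm = x_mm, z_mm = z_mm, times = times,
      cycle_duration_s = cycle_duration_s, venc_cm_s = venc_cm_s,
      plane_id = plane_id, azimuths = azimuths
    ),
    class = "velocity_field"
  )
}

# bilinear interpolation of one frame-slice (matrix [nx, nz]) at points
.bilinear <- function(m, x_grid, z_grid, x, z) {
  dx <- x_grid[2] - x_grid[1]
  dz <- z_grid[2] - z_grid[1]
  fx <- (x - x_grid[1]) / dx
  fz <- (z - z_grid[1]) / dz
  i <- floor(fx)
  j <- floor(fz)
  if (any(i < 0 | i > length(x_grid) - 2 | j < 0 | j > length(z_grid) - 2)) {
    stop("out-of-field: a tracked point left the velocity raster",
      call. = FALSE
    )
  }
  wx <- fx - i
  wz <- fz - j
  i <- i + 1L
  j <- j + 1L
  nx <- length(x_grid)
  idx <- function(ii, jj) (jj - 1L) * nx + ii
  v <- m[idx(i, j)] * (1 - wx) * (1 - wz) +
    m[idx(i + 1L, j)] * wx * (1 - wz) +
    m[idx(i, j + 1L)] * (1 - wx) * wz +
    m[idx(i + 1L, j + 1L)] * wx * wz
  v
}

# velocity (cm/s) at points (x, z) and arbitrary time t, periodic in t with
# linear interpolation between frames
.vf_velocity <- function(vf, x, z, t) {
  T <- vf$cycle_duration_s
  n <- length(vf$times)
  dt <- T / n # frames are equally spaced over the cycle
  tt <- t %% T
  k <- floor(tt / dt)
  w <- tt / dt - k
  k1 <- (k %% n) + 1L
  k2 <- (k1 %% n) + 1L
  vx <- (1 - w) * .bilinear(vf$vx[, , k1], vf$x_mm, vf$z_mm, x, z) +
    w * .bilinear(vf$vx[, , k2], vf$x_mm, vf$z_mm, x, z)
  vz <- (1 - w) * .bilinear(vf$vz[, , k1], vf$x_mm, vf$z_mm, x, z) +
    w * .bilinear(vf$vz[, , k2], vf$x_mm, vf$z_mm, x, z)
  list(vx = vx, vz = vz)
}

#' Track material points through a velocity field
#'
#' @param points `n x 2` matrix of ED positions (mm; columns x, z), e.g. the
#'   `x_mm`/`z_mm` columns of a phantom long-axis segmentation.
#' @param vf a [velocity_field()].
#' @param substeps Runge-Kutta steps per frame interval (default 2).
#' @return object of class `trajectory_set`: list with `positions` (array
#'   `[n_points, 2, n_frames + 1]`, cycle-closure corrected, so the last
#'   frame equals the first), `raw_positions` (before correction),
#'   `closure_error_mm` (per-point drift magnitude before correction),
#'   `times` (frame times incl. the cycle end), `plane_id`.
#' @export
track_points <- function(points, vf, substeps = 2) {
  stopifnot(inherits(vf, "velocity_field"))
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  n <- length(vf$times)
  T <- vf$cycle_duration_s
  dt_frame <- T / n
  np <- nrow(points)
  pos <- array(NA_real_, c(np, 2, n + 1))
  pos[, , 1] <- points
  aliased <- FALSE
  x <- points[, 1]
  z <- points[, 2]
  h <- dt_frame / substeps
  for (k in seq_len(n)) {
    t0 <- (k - 1) * dt_frame
    for (s in seq_len(substeps)) {
      t <- t0 + (s - 1) * h
      # RK4; velocities in cm/s, positions in mm -> factor 10
      k1 <- .vf_velocity(vf, x, z, t)
      k2 <- .vf_velocity(vf, x + 5 * h * k1$vx, z + 5 * h * k1$vz, t + h / 2)
      k3 <- .vf_velocity(vf, x + 5 * h * k2$vx, z + 5 * h * k2$vz, t + h / 2)
      k4 <- .vf_velocity(vf, x + 10 * h * k3$vx, z + 10 * h * k3$vz, t + h)
      if (!aliased) {
        spd <- sqrt(k1$vx^2 + k1$vz^2)
        if (any(spd > vf$venc_cm_s)) {
          warning("velocity above venc encountered: possible aliasing",
            call. = FALSE
          )
          aliased <- TRUE
        }
      }
      x <- x + (10 * h / 6) * (k1$vx + 2 * k2$vx + 2 * k3$vx + k4$vx)
      z <- z + (10 * h / 6) * (k1$vz + 2 * k2$vz + 2 * k3$vz + k4$vz)
    }
    pos[, , k + 1] <- cbind(x, z)
  }
  drift <- pos[, , n + 1, drop = FALSE][, , 1] - points
  if (np == 1) drift <- matrix(drift, 1, 2)
  closure <- sqrt(drift[, 1]^2 + drift[, 2]^2)
  corrected <- pos
  for (k in seq_len(n + 1)) {
    w <- (k - 1) / n
    corrected[, , k] <- pos[, , k] - w * drift
  }
  structure(
    list(
      positions = corrected, raw_positions = pos,
      closure_error_mm = closure,
      times = c(vf$times, T), plane_id = vf$plane_id
    ),
    class = "trajectory_set"
  )
}

#' Build radial and longitudinal strain elements from an ED segmentation
#'
#' Radial elements pair each endocardial point with an epicardial point on
#' the same side: with `radial_pairing = "slice"` (default) the partner is
#' the one at the same level along the long axis, so the element measures the
#' in-plane wall-thickness change (the quantity wall thickening measures on
#' short-axis slices); with `"normal"` the partner closest to the local
#' inward wall-normal line is taken, which tilts the element near the apex
#' and mixes longitudinal motion into the radial reading. Longitudinal
#' elements join consecutive points along each boundary chain.
#'
#' @param ed_points data.frame with columns `role` ("endo"/"epi"), `side`
#'   (azimuth or chain id), `u` (apex-to-base fraction), `x_mm`, `z_mm`,
#'   ordered apex to base within each chain (as produced by
#'   [make_lv_phantom()]).
#' @param radial_pairing `"slice"` or `"normal"` (see above).
#' @return data.frame with columns `i`, `j` (row indices into `ed_points`),
#'   `type` ("radial"/"longitudinal"), `u`, `azimuth_deg`.
#' @export
wall_elements <- function(ed_points, radial_pairing = c("slice", "normal")) {
  radial_pairing <- match.arg(radial_pairing)
  stopifnot(all(c("role", "side", "u", "x_mm", "z_mm") %in% names(ed_points)))
  rows <- list()
  for (sd in unique(ed_points$side)) {
    endo_idx <- which(ed_points$side == sd & ed_points$role == "endo")
    epi_idx <- which(ed_points$side == sd & ed_points$role == "epi")
    ne <- length(endo_idx)
    if (ne >= 2 && length(epi_idx) >= 1) {
      ex <- ed_points$x_mm[endo_idx]
      ez <- ed_points$z_mm[endo_idx]
      for (a in seq_len(ne)) {
        if (radial_pairing == "slice") {
          b <- epi_idx[which.min(abs(ed_points$z_mm[epi_idx] - ez[a]))]
        } else {
          # local tangent from chain neighbors, normal perpendicular to it
          a0 <- max(a - 1, 1)
          a1 <- min(a + 1, ne)
          tang <- c(ex[a1] - ex[a0], ez[a1] - ez[a0])
          tang <- tang / sqrt(sum(tang^2))
          dx <- ed_points$x_mm[epi_idx] - ex[a]
          dz <- ed_points$z_mm[epi_idx] - ez[a]
          # distance of each epi candidate from the normal line
          off <- abs(dx * tang[1] + dz * tang[2])
          b <- epi_idx[which.min(off)]
        }
        rows[[length(rows) + 1]] <- data.frame(
          i = endo_idx[a], j = b, type = "radial",
          u = ed_points$u[endo_idx[a]], azimuth_deg = sd
        )
      }
    }
    for (idx in list(endo_idx, epi_idx)) {
      if (length(idx) >= 2) {
        for (a in seq_len(length(idx) - 1)) {
          rows[[length(rows) + 1]] <- data.frame(
            i = idx[a], j = idx[a + 1], type = "longitudinal",
            u = (ed_points$u[idx[a]] + ed_points$u[idx[a + 1]]) / 2,
            azimuth_deg = sd
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Lagrangian strain of tracked elements
#'
#' `strain(t) = (L(t) - L(0)) / L(0)` for the distance `L` between the two
#' points of each element; strain at frame 1 is exactly zero. Elements whose
#' reference length is below `min_length_mm` are dropped with a warning.
#'
#' @param traj a [track_points()] result.
#' @param elements element table from [wall_elements()] (or any data.frame
#'   with `i`, `j`, `type` and optional `u`, `azimuth_deg`).
#' @param es_frame frame index (into `traj$times`) used for the end-systolic
#'   summary.
#' @param min_length_mm degenerate-element threshold (default 0.5 mm).
#' @return object of class `strain_field`: list with `elements`, `strain`
#'   (matrix `[n_elements, n_frames + 1]`), `es_frame`, and `summary`
#'   (data.frame: type, u, azimuth_deg, es_strain).
#' @export
compute_strain <- function(traj, elements, es_frame, min_length_mm = 0.5) {
  stopifnot(inherits(traj, "trajectory_set"))
  p <- traj$positions
  nf <- dim(p)[3]
  L <- function(k) {
    dx <- p[elements$i, 1, k] - p[elements$j, 1, k]
    dz <- p[elements$i, 2, k] - p[elements$j, 2, k]
    sqrt(dx^2 + dz^2)
  }
  L0 <- L(1)
  bad <- L0 < min_length_mm
  if (any(bad)) {
    warning(sum(bad), " degenerate element(s) excluded (reference length < ",
      min_length_mm, " mm)",
      call. = FALSE
    )
    elements <- elements[!bad, , drop = FALSE]
    L0 <- L0[!bad]
  }
  strain <- matrix(NA_real_, nrow(elements), nf)
  for (k in seq_len(nf)) strain[, k] <- (L(k) - L0) / L0
  smry <- data.frame(
    type = elements$type,
    u = if ("u" %in% names(elements)) elements$u else NA_real_,
    azimuth_deg = if ("azimuth_deg" %in% names(elements)) {
      elements$azimuth_deg
    } else {
      NA_real_
    },
    es_strain = strain[, es_frame]
  )
  structure(
    list(
      elements = elements, strain = strain, es_frame = es_frame,
      summary = smry
    ),
    class = "strain_field"
  )
}

#' Per-segment end-systolic strain from one or more strain fields
#'
#' Pools element-level ES strain (with known polar coordinates) into AHA
#' segments, separately for the radial and longitudinal components.
#'
#' @param ... `strain_field` objects.
#' @return data.frame: segment, radial_strain, longitudinal_strain,
#'   n_elements. Segments with no coverage are absent.
#' @export
segment_strain <- function(...) {
  sm <- do.call(rbind, lapply(list(...), function(s) s$summary))
  sm$segment <- assign_segment(pmin(pmax(sm$u, 0), 1), sm$azimuth_deg)
  out <- data.frame(segment = sort(unique(sm$segment)))
  for (ty in c("radial", "longitudinal")) {
    sub <- sm[sm$type == ty, ]
    v <- tapply(sub$es_strain, factor(sub$segment, levels = out$segment), mean)
    out[[paste0(ty, "_strain")]] <- as.numeric(v)
  }
  out$n_elements <- as.integer(table(factor(sm$segment, levels = out$segment)))
  out
}
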