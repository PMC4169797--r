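#' Wall thickness, thickening and global function from contours
#'
#' Centerline-family thickness measurement: thickness is sampled along rays
#' cast from the mid-wall center (midpoint of the endo- and epicardial
#' centroids) through both contours, at equally spaced azimuths. Wall
#' thickening is the end-systolic minus end-diastolic thickness per chord;
#' fractional wall thickening divides by the end-diastolic thickness.
#'
#' @name geometry_function
NULL

# signed polygon area (shoelace); vertices as n x 2 matrix
.poly_area <- function(p) {
  x <- p[, 1]
  y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# polygon centroid (area-weighted)
.poly_centroid <- function(p) {
  x <- p[, 1]
  y <- p[, 2]
  j <- c(seq_len(nrow(p))[-1], 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# crossing-number point-in-polygon, vectorized over points
.points_in_poly <- function(pts, poly) {
  px <- poly[, 1]
  py <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1)
  inside <- rep(FALSE, nrow(pts))
  for (e in seq_len(nrow(poly))) {
    x1 <- px[e]; y1 <- py[e]; x2 <- px[j[e]]; y2 <- py[j[e]]
    crosses <- (y1 > pts[, 2]) != (y2 > pts[, 2])
    if (any(crosses)) {
      xint <- x1 + (pts[crosses, 2] - y1) * (x2 - x1) / (y2 - y1)
      inside[crosses] <- xor(inside[crosses], pts[crosses, 1] < xint)
    }
  }
  inside
}

# TRUE when any two non-adjacent edges of the polygon intersect
.poly_self_intersects <- function(p) {
  n <- nrow(p)
  j <- c(seq_len(n)[-1], 1)
  a1 <- p
  a2 <- p[j, , drop = FALSE]
  seg_int <- function(p1, p2, q1, q2) {
    d1 <- p2 - p1
    d2 <- q2 - q1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    s <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
    t <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
    s > 1e-9 && s < 1 - 1e-9 && t > 1e-9 && t < 1 - 1e-9
  }
  for (e1 in seq_len(n - 2)) {
    for (e2 in (e1 + 2):n) {
      if (e1 == 1 && e2 == n) next # adjacent via wrap-around
      if (seg_int(a1[e1, ], a2[e1, ], a1[e2, ], a2[e2, ])) return(TRUE)
    }
  }
  FALSE
}

# distance from center c along direction d (unit) to the polygon boundary;
# takes the largest positive ray parameter (outermost crossing)
.ray_poly_distance <- function(center, d, poly) {
  n <- nrow(poly)
  j <- c(seq_len(n)[-1], 1)
  p1x <- poly[, 1] - center[1]
  p1y <- poly[, 2] - center[2]
  p2x <- poly[j, 1] - center[1]
  p2y <- poly[j, 2] - center[2]
  ex <- p2x - p1x
  ey <- p2y - p1y
  den <- d[1] * ey - d[2] * ex
  ok <- abs(den) > 1e-12
  s <- (p1x * ey - p1y * ex) / den # ray parameter
  t <- (p1x * d[2] - p1y * d[1]) / den # edge parameter
  # small slack on the edge parameter so rays through a vertex still hit
  hit <- ok & s > 0 & t >= -1e-9 & t <= 1 + 1e-9
  hit[is.na(hit)] <- FALSE
  if (!any(hit)) {
    return(NA_real_)
  }
  max(s[hit])
}

#' Centerline wall thickness of one slice
#'
#' @param endo,epi contour vertex matrices (`n x 2`, mm), ordered,
#'   non-self-intersecting, endo strictly inside epi.
#' @param n_chords number of equally spaced azimuthal chords (default 80).
#' @param apexbase optional normalized apex-to-base position of the slice,
#'   carried along for AHA mapping.
#' @param validate check contour simplicity and containment (default TRUE).
#' @return object of class `thickness_profile`: list with `azimuth_deg`,
#'   `r_endo_mm`, `r_epi_mm`, `thickness_mm`, `center`, `apexbase`.
#' @export
compute_thickness <- function(endo, epi, n_chords = 80, apexbase = NULL,
                              validate = TRUE) {
  endo <- as.matrix(endo)
  epi <- as.matrix(epi)
  stopifnot(ncol(endo) == 2, ncol(epi) == 2, n_chords >= 4)
  if (validate) {
    if (.poly_self_intersects(endo) || .poly_self_intersects(epi)) {
      stop("invalid geometry: contour is self-intersecting", call. = FALSE)
    }
    if (!all(.points_in_poly(endo, epi))) {
      stop("containment violated: endocardium is not inside the epicardium",
        call. = FALSE
      )
    }
  }
  center <- (.poly_centroid(endo) + .poly_centroid(epi)) / 2
  az <- (seq_len(n_chords) - 1) * 360 / n_chords
  rad <- az * pi / 180
  r_endo <- r_epi <- numeric(n_chords)
  for (i in seq_len(n_chords)) {
    d <- c(cos(rad[i]), sin(rad[i]))
    r_endo[i] <- .ray_poly_distance(center, d, endo)
    r_epi[i] <- .ray_poly_distance(center, d, epi)
  }
  if (any(!is.finite(r_endo)) || any(!is.finite(r_epi))) {
    stop("invalid geometry: a chord ray misses a contour", call. = FALSE)
  }
  th <- r_epi - r_endo
  if (any(th <= 0)) {
    stop("invalid geometry: non-positive wall thickness on a chord",
      call. = FALSE
    )
  }
  structure(
    list(
      azimuth_deg = az, r_endo_mm = r_endo, r_epi_mm = r_epi,
      thickness_mm = th, center = center, apexbase = apexbase
    ),
    class = "thickness_profile"
  )
}

#' Wall thickening and fractional wall thickening
#'
#' `WT = ES thickness - ED thickness` per chord; `FWT = WT / ED thickness`.
#'
#' @param ed,es `thickness_profile` objects on the same chord grid.
#' @return list (class `wall_thickening`) with per-chord `azimuth_deg`,
#'   `wt_mm`, `fwt`, plus `apexbase` and, when the slice position is known, a
#'   per-segment summary data.frame `per_segment` (segment, wt_mm, fwt,
#'   n_chords).
#' @export
compute_wall_thickening <- function(ed, es) {
  stopifnot(inherits(ed, "thickness_profile"), inherits(es, "thickness_profile"))
  if (length(ed$azimuth_deg) != length(es$azimuth_deg) ||
    any(abs(ed$azimuth_deg - es$azimuth_deg) > 1e-9)) {
    stop("chord grids of ED and ES profiles do not match", call. = FALSE)
  }
  wt <- es$thickness_mm - ed$thickness_mm
  fwt <- wt / ed$thickness_mm
  per_segment <- NULL
  if (!is.null(ed$apexbase)) {
    seg <- assign_segment(ed$apexbase, ed$azimuth_deg)
    per_segment <- data.frame(
      segment = sort(unique(seg)),
      wt_mm = as.numeric(tapply(wt, seg, mean)),
      fwt = as.numeric(tapply(fwt, seg, mean)),
      n_chords = as.integer(table(seg))
    )
  }
  structure(
    list(
      azimuth_deg = ed$azimuth_deg, wt_mm = wt, fwt = fwt,
      ed_thickness_mm = ed$thickness_mm, es_thickness_mm = es$thickness_mm,
      apexbase = ed$apexbase, per_segment = per_segment
    ),
    class = "wall_thickening"
  )
}

#' Select analyzable slices by the basal-slice rule
#'
#' The most basal included slice is the most basal one with myocardium in the
#' full 360 degrees of the circumference at end systole; everything from it
#' through the apex is kept.
#'
#' @param full_circumference_es logical vector, ordered base to apex: does
#'   the slice show a full ring of myocardium at ES?
#' @return integer indices of the included slices.
#' @export
select_basal_slices <- function(full_circumference_es) {
  stopifnot(is.logical(full_circumference_es))
  first <- which(full_circumference_es)[1]
  if (is.na(first)) {
    stop("empty selection: no slice has full-circumference myocardium at ES",
      call. = FALSE
    )
  }
  seq(first, length(full_circumference_es))
}

#' Global function from volumes
#'
#' Arithmetic layer shared by contour-based and reported-value workflows:
#' `SV = EDV - ESV` (unless a measured SV is supplied), `EF = 100 SV / EDV`,
#' `CO = SV x HR / 1000`.
#'
#' @param edv_ml,esv_ml end-diastolic and end-systolic cavity volumes (ml).
#' @param hr_bpm heart rate (beats/min); NA gives NA cardiac output.
#' @param sv_ml optional stroke volume overriding `edv - esv`.
#' @param lv_mass_ml optional myocardial volume (ml).
#' @return list of class `global_function` with `edv_ml`, `esv_ml`, `sv_ml`,
#'   `ef_percent`, `hr_bpm`, `co_l_min`, `lv_mass_ml`.
#' @export
global_function <- function(edv_ml, esv_ml, hr_bpm = NA_real_, sv_ml = NULL,
                            lv_mass_ml = NA_real_) {
  stopifnot(edv_ml >= 0, esv_ml >= 0, esv_ml <= edv_ml)
  if (is.null(sv_ml)) sv_ml <- edv_ml - esv_ml
  structure(
    list(
      edv_ml = edv_ml, esv_ml = esv_ml, sv_ml = sv_ml,
      ef_percent = 100 * sv_ml / edv_ml,
      hr_bpm = hr_bpm,
      co_l_min = sv_ml * hr_bpm / 1000,
      lv_mass_ml = lv_mass_ml
    ),
    class = "global_function"
  )
}

#' @export
print.global_function <- function(x, ...) {
  cat(sprintf(
    paste0(
      "EDV %.1f ml  ESV %.1f ml  SV %.1f ml  EF %.1f%%  HR %s bpm  ",
      "CO %s l/min  mass %s ml\n"
    ),
    x$edv_ml, x$esv_ml, x$sv_ml, x$ef_percent,
    format(x$hr_bpm), format(round(x$co_l_min, 2)), format(round(x$lv_mass_ml, 1))
  ))
  invisible(x)
}

# total endocardial cavity area over a stack at frame k (mm^2)
.stack_cavity_area <- function(sax, k) {
  sum(vapply(sax, function(s) {
    fr <- s$frames[[k]]
    if (is.null(fr)) 0 else .poly_area(fr$endo)
  }, numeric(1)))
}

#' Detect the end-systolic frame of a short-axis stack
#'
#' ES is the frame with the minimum summed endocardial cavity area
#' (ED is frame 1 by convention).
#'
#' @param sax short-axis stack as produced by [make_lv_phantom()].
#' @return integer frame index.
#' @export
detect_es_frame <- function(sax) {
  n_frames <- length(sax[[1]]$frames)
  areas <- vapply(seq_len(n_frames), function(k) .stack_cavity_area(sax, k),
    numeric(1)
  )
  which.min(areas)
}

#' Cavity volumes, EF, cardiac output and LV mass by slice summation
#'
#' Volumes are slice area times slice thickness summed over the slices kept
#' by the basal-slice rule; LV mass is reported as the ED myocardial volume
#' in ml (no density conversion).
#'
#' @param sax short-axis stack (base to apex) as from [make_lv_phantom()].
#' @param slice_thickness_mm slice thickness (default 8 mm).
#' @param hr_bpm heart rate for cardiac output.
#' @param ed_frame ED frame index (default 1).
#' @param es_frame ES frame index; detected by [detect_es_frame()] when NULL.
#' @return `global_function` object, with attributes `included_slices`,
#'   `ed_frame`, `es_frame`.
#' @export
compute_volumes_mass <- function(sax, slice_thickness_mm = 8, hr_bpm = NA_real_,
                                 ed_frame = 1, es_frame = NULL) {
  if (is.null(es_frame)) es_frame <- detect_es_frame(sax)
  if (is.null(sax[[1]]$frames[[ed_frame]])) {
    stop("phase error: no contours at the ED frame", call. = FALSE)
  }
  flags <- vapply(sax, function(s) !is.null(s$frames[[es_frame]]), logical(1))
  keep <- select_basal_slices(flags)
  vol <- function(k, role) {
    sum(vapply(sax[keep], function(s) {
      fr <- s$frames[[k]]
      if (is.null(fr)) 0 else .poly_area(fr[[role]])
    }, numeric(1))) * slice_thickness_mm / 1000 # mm^3 -> ml
  }
  edv <- vol(ed_frame, "endo")
  esv <- vol(es_frame, "endo")
  mass <- vol(ed_frame, "epi") - edv
  gf <- global_function(edv, esv, hr_bpm, lv_mass_ml = mass)
  attr(gf, "included_slices") <- keep
  attr(gf, "ed_frame") <- ed_frame
  attr(gf, "es_frame") <- es_frame
  gf
}

#' Per-segment wall thickening over a short-axis stack
#'
#' Runs [compute_thickness()] at ED and ES on every included slice and pools
#' chords into AHA segments.
#'
#' @inheritParams compute_volumes_mass
#' @param n_chords chords per slice.
#' @return list with `per_segment` (segment, ed_thickness_mm,
#'   es_thickness_mm, wt_mm, fwt, n_chords), `es_frame`, `included_slices`.
#' @export
stack_wall_thickening <- function(sax, n_chords = 80, ed_frame = 1,
                                  es_frame = NULL) {
  if (is.null(es_frame)) es_frame <- detect_es_frame(sax)
  flags <- vapply(sax, function(s) !is.null(s$frames[[es_frame]]), logical(1))
  keep <- select_basal_slices(flags)
  rows <- list()
  for (i in keep) {
    s <- sax[[i]]
    ed <- s$frames[[ed_frame]]
    es <- s$frames[[es_frame]]
    ped <- compute_thickness(ed$endo, ed$epi, n_chords,
      apexbase = s$apexbase, validate = FALSE
    )
    pes <- compute_thickness(es$endo, es$epi, n_chords,
      apexbase = s$apexbase, validate = FALSE
    )
    wt <- compute_wall_thickening(ped, pes)
    rows[[length(rows) + 1]] <- data.frame(
      segment = assign_segment(s$apexbase, ped$azimuth_deg),
      ed_thickness_mm = ped$thickness_mm,
      es_thickness_mm = pes$thickness_mm,
      wt_mm = wt$wt_mm, fwt = wt$fwt
    )
  }
  chords <- do.call(rbind, rows)
  agg <- stats::aggregate(
    chords[c("ed_thickness_mm", "es_thickness_mm", "wt_mm", "fwt")],
    by = list(segment = chords$segment), FUN = mean
  )
  agg$n_chords <- as.integer(table(chords$segment))
  list(per_segment = agg, es_frame = es_frame, included_slices = keep)
}
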