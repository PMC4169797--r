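#' AHA 17-segment model utilities
#'
#' The left ventricle is partitioned into 6 basal, 6 mid-ventricular and
#' 4 apical segments plus an apical cap (segment 17). Positions along the
#' long axis are expressed as a normalized apex-to-base fraction
#' (0 = apex tip, 1 = base); azimuth is measured in degrees with the origin
#' at the center of the anterior wall, increasing toward the septum.
#'
#' @name aha17
NULL

# ring boundaries on the apex-to-base fraction
.AHA_CAP_MAX <- 1 / 6
.AHA_APICAL_MAX <- 1 / 3
.AHA_MID_MAX <- 2 / 3

#' Assign polar positions to AHA 17-segment ids
#'
#' @param apexbase numeric vector of apex-to-base fractions in `[0, 1]`
#'   (0 = apex tip, 1 = base).
#' @param azimuth_deg numeric vector of azimuths in degrees (0 = anterior,
#'   increasing toward the septum); recycled against `apexbase`.
#' @return integer vector of segment ids in `1:17`. Longitudinal thirds give
#'   the basal (`2/3 < u <= 1`), mid (`1/3 <= u < 2/3`) and apical rings; the
#'   innermost sixth (`u < 1/6`) is the apical cap, segment 17. Basal and mid
#'   rings have six 60-degree sectors, the apical ring four 90-degree sectors.
#' @examples
#' assign_segment(0.5, 0)    # mid anterior -> 7
#' assign_segment(0.02, 123) # apical cap   -> 17
#' @export
assign_segment <- function(apexbase, azimuth_deg) {
  if (any(!is.finite(apexbase)) || any(apexbase < 0 | apexbase > 1)) {
    stop("apexbase position must lie in [0, 1]", call. = FALSE)
  }
  n <- max(length(apexbase), length(azimuth_deg))
  u <- rep_len(apexbase, n)
  az <- rep_len(azimuth_deg, n) %% 360

  seg <- integer(n)
  cap <- u < .AHA_CAP_MAX
  apical <- !cap & u < .AHA_APICAL_MAX
  mid <- u >= .AHA_APICAL_MAX & u < .AHA_MID_MAX
  basal <- u >= .AHA_MID_MAX

  # 60-degree sectors centered on anterior/anteroseptal/.../anterolateral
  sector6 <- function(a) floor(((a + 30) %% 360) / 60) # 0 = anterior
  # 90-degree apical sectors centered on anterior/septal/inferior/lateral
  sector4 <- function(a) floor(((a + 45) %% 360) / 90)

  seg[basal] <- 1L + sector6(az[basal])
  seg[mid] <- 7L + sector6(az[mid])
  seg[apical] <- 13L + sector4(az[apical])
  seg[cap] <- 17L
  as.integer(seg)
}

#' Construct a polar map raster
#'
#' A polar map is a matrix over (apex-to-base bin, azimuth bin): rows run
#' from the apex (row 1) to the base, columns cover the azimuth in equal
#' bins starting at 0 degrees (anterior). Values may be perfusion counts,
#' infarct transmurality, strain, thickening, or a logical mask.
#'
#' @param values matrix `n_apexbase x n_azimuth`, or a single value to fill.
#' @param n_azimuth,n_apexbase raster dimensions (defaults 36 x 20).
#' @param label quantity name carried along for reporting.
#' @return object of class `polar_map`.
#' @export
polar_map <- function(values = 0, n_azimuth = 36, n_apexbase = 20,
                      label = "value") {
  if (is.matrix(values)) {
    n_apexbase <- nrow(values)
    n_azimuth <- ncol(values)
    m <- values
  } else {
    m <- matrix(values, n_apexbase, n_azimuth)
  }
  structure(m,
    azimuth_centers = (seq_len(n_azimuth) - 0.5) * 360 / n_azimuth,
    apexbase_centers = (seq_len(n_apexbase) - 0.5) / n_apexbase,
    label = label,
    class = c("polar_map", "matrix", "array")
  )
}

#' Evaluate a function of polar position on a raster grid
#'
#' @param fn function of `(apexbase, azimuth_deg)` evaluated at bin centers;
#'   must be vectorized.
#' @inheritParams polar_map
#' @export
polar_map_from_fn <- function(fn, n_azimuth = 36, n_apexbase = 20,
                              label = "value") {
  az <- (seq_len(n_azimuth) - 0.5) * 360 / n_azimuth
  ub <- (seq_len(n_apexbase) - 0.5) / n_apexbase
  m <- outer(ub, az, fn)
  polar_map(m, label = label)
}

#' @export
print.polar_map <- function(x, ...) {
  cat(sprintf(
    "polar_map '%s': %d apex-base x %d azimuth bins, range [%g, %g]\n",
    attr(x, "label"), nrow(x), ncol(x), min(x), max(x)
  ))
  invisible(x)
}

.polar_segments <- function(map) {
  az <- attr(map, "azimuth_centers")
  ub <- attr(map, "apexbase_centers")
  # segment id for every bin center; rows vary over apexbase
  matrix(
    assign_segment(rep(ub, times = length(az)), rep(az, each = length(ub))),
    nrow = length(ub)
  )
}

#' Reduce a polar map (or point samples) to 17 segment values
#'
#' Continuous quantities are averaged per segment (`mode = "mean"`); binary
#' masks are reduced to the covered fraction per segment
#' (`mode = "fraction"`).
#'
#' @param map a `polar_map`.
#' @param mode `"mean"` or `"fraction"`.
#' @return data.frame with columns `segment`, `value`, `n_pixels`
#'   (class `aha17_map`).
#' @export
reduce_polar <- function(map, mode = c("mean", "fraction")) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "polar_map"))
  seg <- .polar_segments(map)
  v <- as.numeric(map)
  if (mode == "fraction") v <- as.numeric(v != 0)
  aha17_from_samples(seg, v)
}

#' Reduce per-sample values with known segment ids to an AHA-17 table
#'
#' @param segment integer segment ids per sample (1..17).
#' @param values numeric values per sample.
#' @return `aha17_map` data.frame (segment, value, n_pixels).
#' @export
aha17_from_samples <- function(segment, values) {
  stopifnot(length(segment) == length(values))
  missing <- setdiff(1:17, unique(segment))
  if (length(missing) > 0) {
    stop(
      "no samples in segment(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out <- data.frame(
    segment = 1:17,
    value = as.numeric(tapply(values, factor(segment, levels = 1:17), mean)),
    n_pixels = as.integer(table(factor(segment, levels = 1:17)))
  )
  class(out) <- c("aha17_map", "data.frame")
  out
}

#' Render 17 segment values onto a polar raster
#'
#' Inverse of [reduce_polar()] for piecewise-constant maps: every bin gets
#' the value of its segment, so reducing the result recovers the input
#' exactly.
#'
#' @param values17 numeric vector of 17 segment values.
#' @inheritParams polar_map
#' @export
polar_from_aha17 <- function(values17, n_azimuth = 36, n_apexbase = 20,
                             label = "value") {
  stopifnot(length(values17) == 17)
  map <- polar_map(0, n_azimuth, n_apexbase, label = label)
  seg <- .polar_segments(map)
  map[] <- values17[seg]
  map
}

#' Fixed azimuths of the standard long-axis imaging planes
#'
#' Each long-axis plane is a meridional cut intersecting the wall at two
#' opposite azimuths: the 2-chamber view crosses anterior/inferior, the
#' 3-chamber view anteroseptal/inferolateral, and the 4-chamber view
#' inferoseptal/anterolateral.
#'
#' @return named list of length-2 azimuth vectors (degrees).
#' @export
lax_plane_azimuths <- function() {
  list(
    "2ch" = c(0, 180),
    "3ch" = c(60, 240),
    "4ch" = c(120, 300)
  )
}
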