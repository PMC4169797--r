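#' File formats
#'
#' Contour sequences travel as JSON (plane id, apex-to-base position, frame
#' times, ordered vertex lists in mm, image convention x-right/y-down,
#' counterclockwise vertices); velocity fields as paired NIfTI volumes (x and
#' z components, cm/s) with a JSON sidecar holding pixel spacing, frame times
#' and the venc; polar maps as CSV rasters (rows = apex-to-base bins from the
#' apex, columns = azimuth bins from the anterior wall).
#'
#' @name io
NULL

#' Write/read a short-axis contour stack as JSON
#'
#' @param sax stack as produced by [make_lv_phantom()].
#' @param times frame times (s).
#' @param path output file.
#' @export
write_contours_json <- function(sax, times, path) {
  slices <- lapply(sax, function(s) {
    list(
      plane_id = s$plane_id, z_mm = s$z_mm, apexbase = s$apexbase,
      full_circumference = s$full_circumference,
      frames = lapply(s$frames, function(fr) {
        if (is.null(fr)) {
          NULL
        } else {
          list(endo = unname(fr$endo), epi = unname(fr$epi))
        }
      })
    )
  })
  jsonlite::write_json(
    list(
      coordinate_convention = "mm, x-right/y-down, vertices counterclockwise",
      frame_times_s = times, slices = slices
    ),
    path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_contours_json
#' @export
read_contours_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  mat <- function(rows) do.call(rbind, lapply(rows, as.numeric))
  sax <- lapply(obj$slices, function(sl) {
    frames <- lapply(sl$frames, function(fr) {
      if (is.null(fr) || is.null(fr$endo)) {
        NULL
      } else {
        list(endo = mat(fr$endo), epi = mat(fr$epi))
      }
    })
    list(
      plane_id = sl$plane_id, z_mm = sl$z_mm, apexbase = sl$apexbase,
      frames = frames,
      full_circumference = as.logical(unlist(sl$full_circumference))
    )
  })
  list(times = as.numeric(unlist(obj$frame_times_s)), sax = sax)
}

#' Write/read a velocity field as NIfTI + JSON sidecar
#'
#' Writes `<prefix>_vx.nii.gz`, `<prefix>_vz.nii.gz` (arrays x, z, frame;
#' cm/s) and `<prefix>.json`.
#'
#' @param vf a [velocity_field()].
#' @param prefix output path prefix.
#' @export
write_velocity_nifti <- function(vf, prefix) {
  sp <- c(vf$x_mm[2] - vf$x_mm[1], vf$z_mm[2] - vf$z_mm[1])
  RNifti::writeNifti(
    RNifti::asNifti(vf$vx, pixdim = c(sp, 1)),
    paste0(prefix, "_vx.nii.gz")
  )
  RNifti::writeNifti(
    RNifti::asNifti(vf$vz, pixdim = c(sp, 1)),
    paste0(prefix, "_vz.nii.gz")
  )
  jsonlite::write_json(
    list(
      plane_id = vf$plane_id, azimuths_deg = vf$azimuths,
      pixel_spacing_mm = sp, origin_mm = c(vf$x_mm[1], vf$z_mm[1]),
      frame_times_s = vf$times, cycle_duration_s = vf$cycle_duration_s,
      venc_cm_s = vf$venc_cm_s, units = "cm/s"
    ),
    paste0(prefix, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(prefix)
}

#' @rdname write_velocity_nifti
#' @export
read_velocity_nifti <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  vx <- as.array(RNifti::readNifti(paste0(prefix, "_vx.nii.gz")))
  vz <- as.array(RNifti::readNifti(paste0(prefix, "_vz.nii.gz")))
  velocity_field(
    vx, vz,
    x_mm = meta$origin_mm[1] + (seq_len(dim(vx)[1]) - 1) * meta$pixel_spacing_mm[1],
    z_mm = meta$origin_mm[2] + (seq_len(dim(vx)[2]) - 1) * meta$pixel_spacing_mm[2],
    times = meta$frame_times_s, cycle_duration_s = meta$cycle_duration_s,
    venc_cm_s = meta$venc_cm_s, plane_id = meta$plane_id,
    azimuths = meta$azimuths_deg
  )
}

#' Write/read a polar map as a CSV raster
#'
#' Rows run from the apex (row 1) to the base, columns over the azimuth from
#' the anterior wall.
#'
#' @param map a `polar_map`.
#' @param path CSV file.
#' @export
write_polar_csv <- function(map, path) {
  stopifnot(inherits(map, "polar_map"))
  m <- matrix(as.numeric(map), nrow(map), ncol(map))
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_polar_csv
#' @param label quantity label for the map read back.
#' @export
read_polar_csv <- function(path, label = "value") {
  m <- as.matrix(utils::read.csv(path, header = TRUE))
  dimnames(m) <- NULL
  polar_map(m, label = label)
}
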