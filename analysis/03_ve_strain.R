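#!/usr/bin/env Rscript
# Velocity-encoded strain: track the ED segmentation through the velocity
# rasters of the three long-axis planes, correct the cycle-closure drift,
# and reduce end-systolic radial/longitudinal strain to the 17 AHA segments.

suppressPackageStartupMessages(library(lvregional))

inp <- "results/phantom"
out <- "results/strain"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (ph in c("pre", "post")) {
  stack <- read_contours_json(file.path(inp, sprintf("contours_%s.json", ph)))
  es_frame <- detect_es_frame(stack$sax)
  # ED segmentation chains are regenerated from the same phantom settings the
  # velocity rasters were produced with (seeds recorded in 01)
  spec <- lv_phantom_spec(
    dysfunction_model = if (ph == "pre") 1 else 0.25,
    seed = if (ph == "pre") 1L else 2L
  )
  phant <- make_lv_phantom(spec)
  fields <- list()
  for (plane in names(lax_plane_azimuths())) {
    vf <- read_velocity_nifti(file.path(inp, sprintf("velocity_%s_%s", ph, plane)))
    pts <- phant$lax[[plane]]$ed_points
    traj <- track_points(cbind(pts$x_mm, pts$z_mm), vf)
    message(sprintf(
      "[%s %s] tracked %d points, max pre-correction closure drift %.4f mm",
      ph, plane, nrow(pts), max(traj$closure_error_mm)
    ))
    fields[[plane]] <- compute_strain(traj, wall_elements(pts),
      es_frame = es_frame
    )
  }
  seg <- do.call(segment_strain, fields)
  seg$phase <- ph
  rows[[ph]] <- seg
}
seg_all <- do.call(rbind, rows)
write.csv(seg_all, file.path(out, "segment_strain.csv"), row.names = FALSE)
message(sprintf(
  "mean ES radial strain pre %.3f -> post %.3f; longitudinal %.3f -> %.3f",
  mean(rows$pre$radial_strain), mean(rows$post$radial_strain),
  mean(rows$pre$longitudinal_strain), mean(rows$post$longitudinal_strain)
))
message("per-segment strain written to ", out)
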