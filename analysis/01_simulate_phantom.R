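#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a deforming-LV phantom before ischemia
# (fully functional wall) and after ischemia (hypokinetic anterior region
# matching the perfusion defect), and write the raw inputs every later stage
# consumes: contour JSON, velocity NIfTI rasters, perfusion and LGE polar
# maps, and the closed-form ground truth.

suppressPackageStartupMessages(library(lvregional))

out <- "results/phantom"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

specs <- list(
  pre = lv_phantom_spec(dysfunction_model = 1, seed = 1L),
  post = lv_phantom_spec(dysfunction_model = 0.25, seed = 2L)
)

for (ph in names(specs)) {
  p <- make_lv_phantom(specs[[ph]])
  write_contours_json(
    p$sax, p$times, file.path(out, sprintf("contours_%s.json", ph))
  )
  for (plane in names(p$velocity)) {
    write_velocity_nifti(
      p$velocity[[plane]], file.path(out, sprintf("velocity_%s_%s", ph, plane))
    )
  }
  message(sprintf(
    "[%s] %d short-axis slices, %d frames, peak in-plane speed %.2f cm/s",
    ph, length(p$sax), length(p$times),
    max(abs(c(p$velocity[["2ch"]]$vx, p$velocity[["2ch"]]$vz)))
  ))
}
post <- make_lv_phantom(specs$post)
write_polar_csv(post$perfusion, file.path(out, "perfusion_counts.csv"))
write_polar_csv(post$lge, file.path(out, "lge_transmurality.csv"))
write.csv(post$truth, file.path(out, "ground_truth.csv"), row.names = FALSE)

tr_es <- phantom_truth(specs$post, u = 1, azimuth_deg = 180, t = 0.5)
message(sprintf(
  "remote base at ES: endo %.1f mm, epi %.2f mm, thickness %.2f mm (ED 8 mm)",
  tr_es$endo_radius_mm, tr_es$epi_radius_mm, tr_es$thickness_mm
))
message("inputs written to ", out)
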