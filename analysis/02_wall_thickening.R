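#!/usr/bin/env Rscript
# Wall thickness, thickening and global function from the contour sequences
# written by 01_simulate_phantom.R: centerline thickness on every analyzable
# short-axis slice (basal-slice rule at end systole), cavity volumes, EF and
# myocardial mass by slice summation.

suppressPackageStartupMessages(library(lvregional))

inp <- "results/phantom"
out <- "results/function"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

hr <- c(pre = 81, post = 113) # reported group means

gf_rows <- list()
seg_rows <- list()
for (ph in c("pre", "post")) {
  stack <- read_contours_json(file.path(inp, sprintf("contours_%s.json", ph)))
  gf <- compute_volumes_mass(stack$sax, slice_thickness_mm = 8, hr_bpm = hr[[ph]])
  wt <- stack_wall_thickening(stack$sax, n_chords = 80)
  message(sprintf(
    "[%s] EDV %.1f ml ESV %.1f ml EF %.1f%% mass %.1f ml (ES frame %d, %d slices kept)",
    ph, gf$edv_ml, gf$esv_ml, gf$ef_percent, gf$lv_mass_ml,
    attr(gf, "es_frame"), length(attr(gf, "included_slices"))
  ))
  gf_rows[[ph]] <- data.frame(
    phase = ph, edv_ml = gf$edv_ml, esv_ml = gf$esv_ml, sv_ml = gf$sv_ml,
    ef_percent = gf$ef_percent, hr_bpm = gf$hr_bpm, co_l_min = gf$co_l_min,
    lv_mass_ml = gf$lv_mass_ml
  )
  seg <- wt$per_segment
  seg$phase <- ph
  seg_rows[[ph]] <- seg
}
write.csv(do.call(rbind, gf_rows), file.path(out, "global_function.csv"),
  row.names = FALSE
)
write.csv(do.call(rbind, seg_rows), file.path(out, "wall_thickening.csv"),
  row.names = FALSE
)
message("global function and per-segment thickening written to ", out)
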