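#!/usr/bin/env Rscript
# Perfusion-based territory classification and myocardial salvage: apply the
# 50%-of-maximum rule to the perfusion polar map, classify the 17 segments
# (ischemic / adjacent / remote), take infarct size from the LGE
# transmurality map, and compute the salvage index MSI = 1 - infarct / AAR.

suppressPackageStartupMessages(library(lvregional))

inp <- "results/phantom"
out <- "results/classification"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_polar_csv(file.path(inp, "perfusion_counts.csv"), "counts")
lge <- read_polar_csv(file.path(inp, "lge_transmurality.csv"), "transmurality")

defect <- quantify_defect(counts)
fractions <- segment_ischemia_fractions(defect$mask)
cls <- classify_segments(fractions)
infarct <- infarct_size_from_transmurality(lge)
salvage <- compute_msi(infarct, defect$extent_pct)

write.csv(cls, file.path(out, "classification.csv"), row.names = FALSE)
write.csv(
  data.frame(
    aar_pct = salvage$aar_pct, infarct_pct = salvage$infarct_pct,
    msi = salvage$msi
  ),
  file.path(out, "salvage.csv"),
  row.names = FALSE
)
message(sprintf(
  "AAR %.1f%% of LV, infarct %.1f%% of LV, MSI %.2f",
  salvage$aar_pct, salvage$infarct_pct, salvage$msi
))
message(sprintf(
  "segments: %d ischemic, %d adjacent, %d remote",
  sum(cls$label == "ischemic"), sum(cls$label == "adjacent"),
  sum(cls$label == "remote")
))
message("classification written to ", out)
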