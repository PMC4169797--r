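#' Perfusion defect, segment classification and myocardial salvage
#'
#' The perfusion defect (area at risk) is all myocardium below 50% of the
#' maximum counts. Segments are classified by their ischemic fraction:
#' more than half ischemic -> ischemic segment; any nonzero ischemia up to
#' half -> adjacent; none -> remote. Myocardial salvage index is
#' `MSI = 1 - infarct size / area at risk` (both as % of the LV).
#'
#' @name ischemia_classify
NULL

#' Quantify a perfusion defect by the 50%-of-maximum rule
#'
#' @param counts `polar_map` of perfusion counts (>= 0, not all zero).
#' @param threshold_fraction cutoff relative to the map maximum (default 0.5).
#' @return list with `mask` (logical `polar_map`, TRUE inside the defect) and
#'   `extent_pct` (% of the polar domain below threshold).
#' @export
quantify_defect <- function(counts, threshold_fraction = 0.5) {
  stopifnot(inherits(counts, "polar_map"))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  mx <- max(counts)
  if (mx <= 0) {
    stop("degenerate input: perfusion map has no positive counts",
      call. = FALSE
    )
  }
  mask <- counts
  mask[] <- counts < threshold_fraction * mx
  attr(mask, "label") <- "ischemic_mask"
  list(mask = mask, extent_pct = 100 * mean(mask))
}

#' Per-segment ischemic fraction of a defect mask
#'
#' @param mask logical `polar_map` (e.g. from [quantify_defect()]).
#' @return numeric vector of 17 fractions in `[0, 1]`, indexed by segment.
#' @export
segment_ischemia_fractions <- function(mask) {
  reduce_polar(mask, mode = "fraction")$value
}

#' Classify the 17 segments as ischemic, adjacent or remote
#'
#' Fraction above 0.5 -> ischemic; in (0, 0.5] -> adjacent; exactly 0 ->
#' remote (a segment with more ischemic than non-ischemic myocardium is
#' ischemic, otherwise adjacent; no ischemia means remote).
#'
#' @param fractions numeric vector of 17 per-segment ischemic fractions.
#' @return data.frame (class `classified_segments`): segment,
#'   ischemia_fraction, label (factor ischemic/adjacent/remote).
#' @export
classify_segments <- function(fractions) {
  if (length(fractions) != 17 || any(fractions < 0 | fractions > 1)) {
    stop("fractions must be 17 values in [0, 1]", call. = FALSE)
  }
  label <- ifelse(fractions > 0.5, "ischemic",
    ifelse(fractions > 0, "adjacent", "remote")
  )
  out <- data.frame(
    segment = 1:17,
    ischemia_fraction = fractions,
    label = factor(label, levels = c("ischemic", "adjacent", "remote"))
  )
  class(out) <- c("classified_segments", "data.frame")
  out
}

#' Infarct size from a transmurality polar map
#'
#' Infarct size as % of the LV is the equally weighted mean transmural extent
#' over the polar domain, times 100.
#'
#' @param lge `polar_map` of infarct transmurality, values in `[0, 1]`.
#' @return infarct size (% of LV).
#' @export
infarct_size_from_transmurality <- function(lge) {
  stopifnot(inherits(lge, "polar_map"))
  if (any(lge < 0 | lge > 1)) {
    stop("transmurality values must lie in [0, 1]", call. = FALSE)
  }
  100 * mean(lge)
}

#' Myocardial salvage index
#'
#' `MSI = 1 - infarct_pct / aar_pct`. Undefined (flagged) when the area at
#' risk is zero; negative salvage (infarct exceeding the area at risk) is
#' returned with a warning, together with a `[0, 1]`-clipped value.
#'
#' @param infarct_pct infarct size (% of LV, >= 0).
#' @param aar_pct area at risk (% of LV, >= 0).
#' @return list (class `salvage_result`): `aar_pct`, `infarct_pct`, `msi`,
#'   `msi_clipped`, `undefined`.
#' @export
compute_msi <- function(infarct_pct, aar_pct) {
  stopifnot(infarct_pct >= 0, aar_pct >= 0)
  if (aar_pct == 0) {
    out <- list(
      aar_pct = 0, infarct_pct = infarct_pct, msi = NA_real_,
      msi_clipped = NA_real_, undefined = TRUE
    )
    class(out) <- "salvage_result"
    return(out)
  }
  msi <- 1 - infarct_pct / aar_pct
  if (msi < 0) {
    warning("negative salvage: infarct size exceeds the area at risk",
      call. = FALSE
    )
  }
  out <- list(
    aar_pct = aar_pct, infarct_pct = infarct_pct, msi = msi,
    msi_clipped = min(max(msi, 0), 1), undefined = FALSE
  )
  class(out) <- "salvage_result"
  out
}

#' @export
print.salvage_result <- function(x, ...) {
  if (x$undefined) {
    cat("MSI undefined (area at risk = 0)\n")
  } else {
    cat(sprintf(
      "AAR %.1f%% of LV, infarct %.1f%% of LV, MSI %.2f\n",
      x$aar_pct, x$infarct_pct, x$msi
    ))
  }
  invisible(x)
}
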