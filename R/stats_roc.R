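#' Paired statistics and ROC threshold scans
#'
#' Paired pre/post comparisons use the Wilcoxon signed-rank test (global
#' hemodynamics) or the paired t-test (regional thickening and strain), with
#' 0.05 as the significance level. Discrimination thresholds between
#' ischemic, adjacent and remote territories come from a 1000-step ROC scan
#' from the minimum to the maximum of each metric; the optimum maximizes the
#' Youden index (sensitivity + specificity - 1).
#'
#' @name stats_roc
NULL

#' Paired pre/post test
#'
#' @param pre,post equal-length paired samples (n >= 2).
#' @param test `"t"` (paired t-test) or `"wilcoxon"` (signed rank).
#' @return list: `statistic`, `p_value`, `method`, `significant` (p < 0.05),
#'   `degenerate` (TRUE when all paired differences are identical, so the
#'   test statistic is undefined; p is NA then).
#' @export
paired_tests <- function(pre, post, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(pre) != length(post)) {
    stop("pre and post must be paired (equal length)", call. = FALSE)
  }
  if (length(pre) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- post - pre
  if (stats::sd(d) == 0) {
    return(list(
      statistic = NA_real_, p_value = NA_real_,
      method = test, significant = NA, degenerate = TRUE
    ))
  }
  if (test == "t") {
    ht <- stats::t.test(post, pre, paired = TRUE)
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(post, pre, paired = TRUE, exact = FALSE)
    )
  }
  list(
    statistic = unname(ht$statistic), p_value = ht$p.value,
    method = test, significant = ht$p.value < 0.05, degenerate = FALSE
  )
}

#' ROC threshold scan
#'
#' Sensitivity and specificity are evaluated at `n_steps` equally spaced
#' thresholds from the minimum to the maximum of `values`. With
#' `direction = "below"` a value strictly below the threshold is called
#' positive (low wall thickening / low radial strain marks ischemia); with
#' `"above"`, strictly above (high, i.e. less negative, longitudinal strain).
#' The optimal threshold maximizes the Youden index; ties are broken toward
#' higher specificity, then toward the middle of the tied run.
#'
#' @param values numeric metric per observation.
#' @param positive logical vector: TRUE for the positive class.
#' @param n_steps number of thresholds (default 1000).
#' @param direction `"below"` or `"above"`.
#' @param comparison label carried to the output (e.g. "ischemic-vs-rest").
#' @return object of class `roc_result`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `youden`, `optimal_threshold`,
#'   `optimal_sensitivity`, `optimal_specificity`, `direction`, `comparison`.
#' @export
roc_scan <- function(values, positive, n_steps = 1000,
                     direction = c("below", "above"), comparison = "") {
  direction <- match.arg(direction)
  stopifnot(length(values) == length(positive))
  positive <- as.logical(positive)
  if (!any(positive) || all(positive)) {
    stop("class error: both classes must be nonempty", call. = FALSE)
  }
  thr <- seq(min(values), max(values), length.out = n_steps)
  pos_v <- values[positive]
  neg_v <- values[!positive]
  if (direction == "below") {
    sens <- vapply(thr, function(h) mean(pos_v < h), numeric(1))
    spec <- vapply(thr, function(h) mean(neg_v >= h), numeric(1))
  } else {
    sens <- vapply(thr, function(h) mean(pos_v > h), numeric(1))
    spec <- vapply(thr, function(h) mean(neg_v <= h), numeric(1))
  }
  youden <- sens + spec - 1
  best <- which(youden > max(youden) - 1e-12)
  best <- best[spec[best] > max(spec[best]) - 1e-12]
  opt <- best[ceiling(length(best) / 2)]
  structure(
    list(
      thresholds = thr, sensitivity = sens, specificity = spec,
      youden = youden,
      optimal_threshold = thr[opt],
      optimal_sensitivity = sens[opt],
      optimal_specificity = spec[opt],
      direction = direction, comparison = comparison
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC %s (positive %s threshold): cutoff %.4g, sens %.0f%%, spec %.0f%%\n",
    x$comparison, x$direction, x$optimal_threshold,
    100 * x$optimal_sensitivity, 100 * x$optimal_specificity
  ))
  invisible(x)
}

#' Sensitivity/specificity of the adjacent band
#'
#' A value is called adjacent when it lies strictly between the lower and
#' upper cutoffs (the ischemic and remote optima, in metric order).
#'
#' @param lower,upper band limits; `lower < upper` required.
#' @param values metric per observation.
#' @param is_adjacent logical vector: TRUE for truly adjacent observations.
#' @return list: `lower`, `upper`, `sensitivity`, `specificity`.
#' @export
adjacent_band <- function(lower, upper, values, is_adjacent) {
  if (!(lower < upper)) {
    stop("band error: empty band interval (lower >= upper)", call. = FALSE)
  }
  stopifnot(length(values) == length(is_adjacent))
  inside <- values > lower & values < upper
  list(
    lower = lower, upper = upper,
    sensitivity = mean(inside[is_adjacent]),
    specificity = mean(!inside[!is_adjacent])
  )
}

# direction of the ischemic comparison per metric (remote uses the opposite)
.METRIC_DIRECTION <- c(
  wall_thickening_mm = "below",
  radial_strain = "below",
  longitudinal_strain = "above"
)

#' Threshold table for discriminating ischemic, adjacent and remote segments
#'
#' For each metric, ischemic segments are compared against adjacent and
#' remote combined, and remote segments against ischemic and adjacent
#' combined; the adjacent band is the interval between the two optima.
#' Sensitivity and specificity are reported as integer percentages.
#'
#' @param data data.frame with a `class` column (ischemic/adjacent/remote)
#'   and the metric columns in `metrics`.
#' @param metrics named metric columns to scan (default: wall thickening,
#'   radial and longitudinal strain).
#' @param n_steps thresholds per scan.
#' @return list with `table` (data.frame: metric, comparison, threshold_low,
#'   threshold_high, sensitivity_pct, specificity_pct) and `roc` (the
#'   underlying `roc_result` objects).
#' @export
roc_table <- function(data, metrics = names(.METRIC_DIRECTION),
                      n_steps = 1000) {
  stopifnot("class" %in% names(data), all(metrics %in% names(data)))
  rows <- list()
  rocs <- list()
  for (m in metrics) {
    dir_isch <- .METRIC_DIRECTION[[m]]
    dir_rem <- if (dir_isch == "below") "above" else "below"
    v <- data[[m]]
    r_isch <- roc_scan(v, data$class == "ischemic", n_steps, dir_isch,
      comparison = paste0(m, ":ischemic-vs-rest")
    )
    r_rem <- roc_scan(v, data$class == "remote", n_steps, dir_rem,
      comparison = paste0(m, ":remote-vs-rest")
    )
    band_lims <- sort(c(r_isch$optimal_threshold, r_rem$optimal_threshold))
    band <- adjacent_band(
      band_lims[1], band_lims[2], v, data$class == "adjacent"
    )
    pct <- function(x) as.integer(round(100 * x))
    rows[[length(rows) + 1]] <- data.frame(
      metric = m,
      comparison = c("ischemic", "adjacent", "remote"),
      threshold_low = c(NA, band$lower, NA),
      threshold_high = c(NA, band$upper, NA),
      threshold = c(r_isch$optimal_threshold, NA, r_rem$optimal_threshold),
      direction = c(dir_isch, "band", dir_rem),
      sensitivity_pct = pct(c(
        r_isch$optimal_sensitivity, band$sensitivity, r_rem$optimal_sensitivity
      )),
      specificity_pct = pct(c(
        r_isch$optimal_specificity, band$specificity, r_rem$optimal_specificity
      ))
    )
    rocs[[paste0(m, "_ischemic")]] <- r_isch
    rocs[[paste0(m, "_remote")]] <- r_rem
  }
  list(table = do.call(rbind, rows), roc = rocs)
}
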