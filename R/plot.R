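#' Bullseye and ROC figures
#'
#' @name figures
NULL

#' Bullseye (polar) plot of 17 segment values
#'
#' Renders the AHA bullseye with the apex at the center, anterior wall at the
#' top, septum to the left.
#'
#' @param values17 numeric vector of 17 segment values, or an `aha17_map`.
#' @param title plot title.
#' @param limits optional fill limits.
#' @return a ggplot object.
#' @export
plot_bullseye <- function(values17, title = NULL, limits = NULL) {
  if (inherits(values17, "aha17_map")) values17 <- values17$value
  stopifnot(length(values17) == 17)
  map <- polar_from_aha17(values17, n_azimuth = 72, n_apexbase = 40)
  az <- attr(map, "azimuth_centers")
  ub <- attr(map, "apexbase_centers")
  df <- expand.grid(u = ub, az = az)
  df$value <- as.numeric(map)
  daz <- 360 / length(az)
  du <- 1 / length(ub)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = az - daz / 2, xmax = az + daz / 2,
      ymin = u - du / 2, ymax = u + du / 2, fill = value
    )) +
    # anterior at the top, azimuth increasing toward the septum on the left
    ggplot2::coord_polar(theta = "x", start = pi, direction = -1) +
    ggplot2::scale_fill_viridis_c(limits = limits) +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(hjust = 0.5))
}

#' ROC curve with the optimal operating point marked
#'
#' @param roc a `roc_result` from [roc_scan()].
#' @return a ggplot object (1 - specificity vs sensitivity, red marker at the
#'   Youden optimum).
#' @export
plot_roc <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  df <- data.frame(fpr = 1 - roc$specificity, tpr = roc$sensitivity)
  ggplot2::ggplot(df, ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::annotate("point",
      x = 1 - roc$optimal_specificity, y = roc$optimal_sensitivity,
      colour = "red", size = 3
    ) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = roc$comparison,
      x = "1 - specificity", y = "sensitivity"
    ) +
    ggplot2::theme_minimal()
}
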