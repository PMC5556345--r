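# ggplot2 figures: person-item (Wright) maps and item characteristic curves.

#' Person-item targeting map
#'
#' The classic two-panel targeting figure on one logit axis: person counts
#' above the axis, item-threshold counts below, with dashed lines marking
#' the instrument's coverage bounds (lowest and highest threshold).
#'
#' @param object A `vfq_targeting` from [targeting_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vfq_targeting <- function(object, ...) {
  bins <- object$bins
  d <- dplyr::bind_rows(
    mutate(bins, what = "Persons", count = .data$persons),
    mutate(bins, what = "Item thresholds", count = -.data$thresholds)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$count,
                                  fill = .data$what)) +
    ggplot2::geom_col(width = bins$upper[1] - bins$lower[1], colour = "grey30",
                      linewidth = 0.2) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = c(object$threshold_min,
                                       object$threshold_max),
                        linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c("Persons" = "#4477AA",
                                          "Item thresholds" = "#EE6677")) +
    ggplot2::labs(x = "Location (logits)", y = "Count (thresholds shown downwards)",
                  fill = NULL,
                  title = "Scale-to-sample targeting",
                  subtitle = sprintf(
                    "%.1f%% of persons above instrument coverage; %.1f%% at maximum raw score",
                    100 * object$prop_above_highest_threshold,
                    100 * object$prop_ceiling)) +
    ggplot2::theme_minimal()
}

#' Item threshold map for a calibration
#'
#' Items on the vertical axis, thresholds as points on the logit axis with
#' the item location marked; the display that reveals disordered thresholds.
#'
#' @param object A `rasch_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rasch_fit <- function(object, ...) {
  td <- tidy(object)
  ord <- object$calibration$item[order(object$calibration$location)]
  td$item <- factor(td$item, levels = ord)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$threshold, y = .data$item)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$threshold_index)),
                        size = 2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$location), shape = 3, size = 2,
                        colour = "black") +
    ggplot2::labs(x = "Location (logits)", y = NULL,
                  colour = "Threshold",
                  title = "Item thresholds (+ = item location)") +
    ggplot2::theme_minimal()
}

#' Item characteristic curves
#'
#' Model-expected score curves for each calibrated item.
#'
#' @param fit A `rasch_fit` or `vfq_calibration`.
#' @param theta_range Range of the location grid (logits).
#' @param n_points Grid resolution.
#' @return A ggplot object.
#' @export
plot_icc <- function(fit, theta_range = c(-6, 6), n_points = 121) {
  cal <- as_calibration(fit)
  grid <- seq(theta_range[1], theta_range[2], length.out = n_points)
  d <- purrr::map_dfr(seq_len(nrow(cal)), function(i) {
    mutate(pcm_icc(cal$thresholds[[i]], grid), item = cal$item[i])
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$theta, y = .data$expected,
                                  colour = .data$item)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Location (logits)", y = "Expected score",
                  colour = NULL, title = "Item characteristic curves") +
    ggplot2::theme_minimal()
}
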