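#' Plot a cell's area and constriction-rate series
#'
#' @param tracks Tidy tracks (`cell_id`, `time_s`, `area_um2`).
#' @param cells Cell IDs to show (default: first three).
#' @param frame_interval Seconds between frames (for the rate panel).
#' @return A ggplot object.
#' @export
plot_pulses <- function(tracks, cells = NULL, frame_interval) {
  if (is.null(cells)) cells <- head(unique(tracks$cell_id), 3)
  d <- tracks[tracks$cell_id %in% cells, ]
  d <- area_rate(d, frame_interval)
  d <- tidyr::pivot_longer(
    d, c("area_um2", "rate_um2_min"),
    names_to = "what", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s / 60, .data$value,
                                  colour = factor(.data$cell_id))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ what, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          area_um2 = "area (µm²)",
                          rate_um2_min = "rate (µm²/min)"))) +
    ggplot2::labs(x = "time (min)", y = NULL, colour = "cell") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.xcorr_fun <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag, .data$coefficient)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line() +
    ggplot2::annotate("point", x = attr(object, "lag_at_max"),
                      y = attr(object, "max_coef"), colour = "orange") +
    ggplot2::labs(x = "lag (frames)", y = "cross-correlation") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.coupling_analysis <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(what = "observed", coef = object$cells$max_coef),
    tibble::tibble(what = paste0("surrogate (", object$surrogate_kind,
                                 ")"),
                   coef = object$null$coef))
  ggplot2::ggplot(d, ggplot2::aes(.data$what, .data$coef)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "max cross-correlation coefficient") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.retraction_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_s,
                                       .data$speed_smooth_um_s)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(y = .data$speed_um_s), size = 0.5,
                        alpha = 0.5) +
    ggplot2::labs(x = "time (s)", y = "retraction speed (µm/s)") +
    ggplot2::theme_minimal()
}

#' Box plot of maximum retraction speeds per stage-angle bin
#'
#' @param x An `angle_bins` object.
#' @return A ggplot object.
#' @export
plot_angle_bins <- function(x) {
  stopifnot(inherits(x, "angle_bins"))
  d <- x$data
  d$bin <- stats::reorder(d$bin, d$bin_lo)
  ggplot2::ggplot(d, ggplot2::aes(.data$bin, .data$max_speed)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "opening-angle bin (°)",
                  y = "max retraction speed (µm/s)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
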