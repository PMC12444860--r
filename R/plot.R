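#' Kymograph heatmap of a ring profile series
#'
#' Time runs along x, the 21 angular sectors along y, fill is the sector
#' mean intensity — the standard view for judging whether recruitment is
#' uniform around the ring or one-sided (e.g. during a pore opening).
#'
#' @param series a `pp_ring_series`.
#' @return A ggplot object.
#' @export
plot_kymograph <- function(series) {
  stopifnot(inherits(series, "pp_ring_series"))
  df <- as_tibble(series) |>
    tidyr::pivot_longer(dplyr::starts_with("s"), names_to = "sector",
                        values_to = "intensity") |>
    dplyr::mutate(sector = as.integer(sub("^s", "", .data$sector)))
  ggplot2::ggplot(df, ggplot2::aes(.data$t_min, .data$sector,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "intensity") +
    ggplot2::labs(x = "time (min)", y = "angular sector",
                  title = sprintf("track %s (%s)", series$track_id,
                                  series$state)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pp_ring_series <- function(object, ...) plot_kymograph(object)

#' Ring-mean trace with detected pulses
#'
#' @param series a normalised `pp_ring_series`.
#' @param params a [pulse_params()] object.
#' @return A ggplot object.
#' @export
plot_trace <- function(series, params = pulse_params()) {
  stopifnot(inherits(series, "pp_ring_series"))
  df <- tibble(t_min = (series$frames - series$frames[1]) *
                 series$frame_interval_s / 60,
               ring_mean = series$ring_mean)
  ev <- detect_pulses(series, params)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$t_min, .data$ring_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = params$fade_threshold,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time since engulfment (min)",
                  y = "normalised ring mean",
                  title = sprintf("track %s: %d pulse(s)",
                                  series$track_id, nrow(ev))) +
    ggplot2::theme_minimal()
  if (nrow(ev)) {
    p <- p + ggplot2::geom_point(
      data = df[ev$peak, ], colour = "red", size = 2)
  }
  p
}

#' Aligned cohort mean with standard-deviation ribbon
#'
#' @param aligned result of [align_and_average()].
#' @return A ggplot object.
#' @export
plot_aligned <- function(aligned) {
  df <- aligned$summary
  ggplot2::ggplot(df, ggplot2::aes(.data$t_min, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time since engulfment (min)",
                  y = "ring mean (mean +/- s.d.)") +
    ggplot2::theme_minimal()
}

#' Per-neutrophil pulsing-fraction distribution (violin-style data)
#'
#' @param summary a [pulsing_summary()] result.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pp_pulsing_summary <- function(object, ...) {
  df <- object$per_neutrophil
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$pct_pulsing)) +
    ggplot2::geom_violin(fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "pulsing phagosomes per neutrophil (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
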