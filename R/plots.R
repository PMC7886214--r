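#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the package's result types: a quiver
#' plot for velocity fields, the VED time course (with detected peaks when
#' supplied), the Doppler envelope, and a TVED comparison bar chart. All
#' return ggplot objects for further styling.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @name mitralflow-plots
NULL

#' @rdname mitralflow-plots
#' @param arrow_scale Arrow length per m/s, in m (default auto).
#' @export
autoplot.velocity_field <- function(object, arrow_scale = NULL, ...) {
  d <- tibble::as_tibble(object) |> dplyr::filter(!.data$mask)
  if (is.null(arrow_scale)) {
    vmax <- max(sqrt(d$u_mps^2 + d$v_mps^2), 1e-12)
    arrow_scale <- 1.5 * attr(object, "spacing_m") / vmax
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$x_m, .data$y_m)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$x_m + arrow_scale * .data$u_mps,
                   yend = .data$y_m + arrow_scale * .data$v_mps,
                   colour = sqrt(.data$u_mps^2 + .data$v_mps^2)),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.04, "inches"))) +
    ggplot2::scale_colour_viridis_c(name = "|v| (m/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' @rdname mitralflow-plots
#' @param peaks Optional `ved_peaks` from [detect_peaks()].
#' @export
autoplot.ved_series <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$t_s, .data$ved_W_per_m)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "VED (W/m)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    p <- p + ggplot2::geom_point(
      data = tibble::as_tibble(peaks),
      ggplot2::aes(.data$time_s, .data$value_W_per_m),
      colour = "firebrick", size = 2)
  }
  p
}

#' @rdname mitralflow-plots
#' @export
autoplot.doppler_envelope <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$t_s, .data$v_mps)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "velocity (m/s)") +
    ggplot2::theme_minimal()
}

#' @rdname mitralflow-plots
#' @export
autoplot.run_comparison <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::filter(!is.na(.data$value_a)) |>
    tidyr::pivot_longer(c("value_a", "value_b"),
                        names_to = "run", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$metric, .data$value,
                                  fill = .data$run)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot co-registered LA/LV pressure traces
#'
#' @param la,lv `pressure_trace` tibbles.
#' @param windows Optional diastolic windows from [diastolic_windows()],
#'   shaded.
#' @return A ggplot object.
#' @export
plot_pressure_traces <- function(la, lv, windows = NULL) {
  d <- dplyr::bind_rows(tibble::as_tibble(la), tibble::as_tibble(lv))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$t_s, .data$p_mmHg,
                                       colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "pressure (mmHg)", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(windows) && nrow(windows) > 0) {
    p <- p + ggplot2::geom_rect(
      data = windows, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      alpha = 0.12, fill = "seagreen")
  }
  p
}
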