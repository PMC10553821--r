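# ggplot2 methods for the package's result types.

#' @rdname dermadisp-generics
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_min,
                                       y = .data$msd_um2)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::scale_size_continuous(name = "pairs") +
    ggplot2::labs(x = "lag (min)", y = expression(MSD ~ (mu * m^2)),
                  title = "Time-ensemble mean squared displacement") +
    ggplot2::theme_minimal()
}

#' @rdname dermadisp-generics
#' @export
autoplot.dd_diffusion_fit <- function(object, ...) {
  autoplot(object$curve) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::labs(subtitle = sprintf("slope = %.4g um^2/min (D = %.4g)",
                                     object$slope, object$D))
}

#' @rdname dermadisp-generics
#' @export
autoplot.dd_variogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_um,
                                       y = .data$gamma_deg2)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::scale_size_continuous(name = "pairs") +
    ggplot2::labs(x = "distance (um)",
                  y = expression(semivariance ~ (deg^2)),
                  title = "Angular variogram") +
    ggplot2::theme_minimal()
}

#' @rdname dermadisp-generics
#' @export
autoplot.dd_variogram_fit <- function(object, ...) {
  vg <- object$variogram
  hs <- seq(0, max(vg$lag_um), length.out = 200)
  line <- tibble(lag_um = hs, gamma_deg2 = predict_variogram(object, hs))
  autoplot(vg) +
    ggplot2::geom_line(data = line, colour = "firebrick") +
    ggplot2::labs(subtitle = sprintf(
      "nugget-to-sill %.2f; effective range(s): %s um",
      object$nugget_to_sill,
      paste(signif(object$effective_ranges, 3), collapse = ", ")))
}

#' @rdname dermadisp-generics
#' @export
autoplot.dd_randomness_map <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$x_um, y = .data$y_um)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$angle_deg)) +
    ggplot2::geom_point(data = dplyr::filter(object$grid, .data$random),
                        colour = "black", size = 0.1, alpha = 0.4) +
    ggplot2::scale_fill_gradientn(colours = grDevices::hcl.colors(12),
                                  name = "kriged angle") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (um)", y = "y (um)",
      title = sprintf("Randomness map (ratio %.2f at alpha = %g)",
                      object$randomness_ratio, object$alpha)) +
    ggplot2::theme_minimal()
}

#' Cumulative condensate-entry plot
#'
#' @param events entry events from [detect_entries()].
#' @param tracks the track tibble the events came from.
#' @return A ggplot of per-group cumulative entry fractions over time.
#' @export
plot_entry_curves <- function(events, tracks) {
  curve <- cumulative_entry_curve(events, tracks)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$rel_time_min,
                                      y = .data$cum_fraction,
                                      colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(values = c(dividing = "#2166ac",
                                            non_dividing = "#1b7837")) +
    ggplot2::labs(x = "time (min, relative to mitosis / first frame)",
                  y = "cumulative fraction entering",
                  title = "Condensate entry") +
    ggplot2::theme_minimal()
}
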