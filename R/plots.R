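#' Plot a fitted TDT curve with its trials
#'
#' Shows the fitted tolerance-time curve (log10 tolerable minutes against
#' temperature) together with each trial plotted at its mean knockdown
#' temperature and the effective exposure time of its ramp
#' (`z / (rate * ln 10)` minutes, the duration over which a linear ramp
#' accumulates most of its injury).
#'
#' @param object A `tdt_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tdt_fit
#' @export
autoplot.tdt_fit <- function(object, ...) {
  p <- object$params
  temps <- seq(
    min(object$data$mean_knockdown) - 2,
    max(object$data$mean_knockdown) + 2,
    length.out = 200
  )
  curve_df <- tibble::tibble(
    temp = temps,
    minutes = tolerable_time(p, temps)
  )
  trial_df <- dplyr::mutate(object$data,
    eff_minutes = p$z / (.data$heating_rate * log(10))
  )
  ggplot2::ggplot(curve_df, ggplot2::aes(x = .data$temp, y = .data$minutes)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(
      data = trial_df,
      ggplot2::aes(x = .data$mean_knockdown, y = .data$eff_minutes),
      shape = 21, fill = "grey30", size = 2.5
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Temperature (°C)",
      y = "Tolerable exposure (min, log scale)",
      title = sprintf(
        "TDT curve: z = %.2f °C/log10(min), static limit %.1f °C at %g min",
        p$z, p$t_static, p$t_ref
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot logger temperature traces by site
#'
#' @param series Logger readings; see [as_logger_series()].
#' @param band Optional two-element numeric: shade this temperature band.
#' @return A ggplot, faceted by site.
#' @export
plot_logger_series <- function(series, band = NULL) {
  series <- as_logger_series(series)
  g <- ggplot2::ggplot(series, ggplot2::aes(x = .data$timestamp, y = .data$temp_c)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$site_id), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Water temperature (°C)") +
    ggplot2::theme_minimal()
  if (!is.null(band)) {
    g <- g + ggplot2::annotate("rect",
      xmin = min(series$timestamp), xmax = max(series$timestamp),
      ymin = band[1L], ymax = band[2L], alpha = 0.15, fill = "firebrick"
    )
  }
  g
}

#' Plot observed exposure against tolerable exposure per band
#'
#' Bar-and-line comparison of the mean observed daily minutes in each
#' temperature band against the model's tolerable duration, per site and
#' species - the exposure-versus-tolerance comparison that identifies bands
#' where daily heat doses exceed what the tolerance curve allows.
#'
#' @param verdicts Output of [run_compare()].
#' @return A ggplot.
#' @export
plot_exposure_comparison <- function(verdicts) {
  verdicts <- dplyr::mutate(verdicts,
    band = sprintf("[%g, %g)", .data$band_lo, .data$band_hi)
  )
  ggplot2::ggplot(verdicts, ggplot2::aes(x = .data$band)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed_min, fill = .data$verdict),
      width = 0.6
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$tolerable_min), shape = 95, size = 8) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$species),
      cols = ggplot2::vars(.data$site_id)
    ) +
    ggplot2::scale_fill_manual(values = c(EXCEEDS = "firebrick", WITHIN = "grey60")) +
    ggplot2::labs(
      x = "Temperature band (°C)",
      y = "Minutes per day",
      fill = NULL,
      caption = "Bars: observed mean daily exposure; dashes: tolerable duration"
    ) +
    ggplot2::theme_minimal()
}
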