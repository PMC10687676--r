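#' Bland-Altman plot
#'
#' Scatter of pairwise means against differences, with a solid blue line at
#' the mean bias and dashed red lines at the 95% limits of agreement
#' (bias +/- 1.96 SD of the differences).
#'
#' @param object A `bland_altman` result.
#' @param xlab,ylab Axis labels.
#' @param ... Unused.
#' @return A ggplot object; deterministic given the input.
#' @export
autoplot.bland_altman <- function(object, xlab = "Mean of methods (steps)",
                                  ylab = "Difference (steps)", ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$mean_bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(
      x = xlab, y = ylab,
      subtitle = sprintf("bias %.1f, LoA (%.1f, %.1f), n = %d",
                         object$mean_bias, object$loa_low, object$loa_high,
                         object$n)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write a Bland-Altman plot to file
#'
#' @param result A `bland_altman` result.
#' @param path Output path (`.png`, `.svg`, or `.pdf`).
#' @param width,height Size in inches.
#' @return `path`, invisibly.
#' @export
bland_altman_plot <- function(result, path, width = 6, height = 4) {
  if (!inherits(result, "bland_altman")) {
    abort("bland_altman_plot needs a bland_altman result",
          class = "stepwave_insufficient_data")
  }
  p <- autoplot(result)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}

#' Plot a cadence series
#'
#' Per-second cadence over time, walking windows highlighted.
#'
#' @param object A `cadence_series`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cadence_series <- function(object, ...) {
  df <- as_tibble(object)
  df$walking <- ifelse(is.na(df$walking), FALSE, df$walking)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_start, y = .data$cadence,
                                   colour = .data$walking)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70",
                                            `TRUE` = "steelblue")) +
    ggplot2::labs(x = "Time (s)", y = "Cadence (steps/s)",
                  colour = "Walking") +
    ggplot2::theme_minimal()
}

#' Plot a scalogram
#'
#' Time-frequency heat map of wavelet coefficient magnitudes; the walking
#' ridge appears as a bright horizontal band at the cadence.
#'
#' @param object A `scalogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scalogram <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time, y = .data$freq,
                               fill = .data$coefficient)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)",
                  fill = "|coefficient| (g)") +
    ggplot2::theme_minimal()
}
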