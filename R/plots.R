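#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a power spectral density
#'
#' One line per channel (alpha-blended) plus the channel-mean density, on a
#' log10 power scale.
#'
#' @param object a `psd_result`.
#' @param fmax upper frequency limit of the plot, Hz.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.psd_result <- function(object, fmax = 40, ...) {
  df <- tidy.psd_result(object)
  df <- df[df$freq > 0 & df$freq <= fmax, ]
  mean_df <- df |>
    dplyr::group_by(.data$freq) |>
    dplyr::summarise(power = mean(.data$power), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$channel), alpha = 0.15,
                       linewidth = 0.2) +
    ggplot2::geom_line(data = mean_df, colour = "firebrick",
                       linewidth = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)",
                  y = expression(PSD ~ (mu * V^2 / Hz))) +
    ggplot2::theme_minimal()
}

#' Plot an evoked waveform as a butterfly plot
#'
#' @param object an `evoked_waveform`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.evoked_waveform <- function(object, ...) {
  df <- tibble::tibble(
    channel = rep(rownames(object$mean), times = ncol(object$mean)),
    time = rep(object$times, each = nrow(object$mean)),
    amplitude = as.numeric(object$mean))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude,
                                   group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.3, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time (ms)", y = expression(amplitude ~ (mu * V))) +
    ggplot2::theme_minimal()
}

#' Plot a GFPt series with detected component peaks
#'
#' @param object a `gfp_series`.
#' @param peaks optional [find_peaks()] tibble to annotate.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gfp_series <- function(object, peaks = NULL, ...) {
  df <- tibble::tibble(time = object$times, gfp = object$gfp)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$gfp)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (ms)", y = expression(GFPt ~ (mu * V))) +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(time = peaks$latency, gfp = peaks$amplitude),
      colour = "firebrick", size = 2) +
      ggplot2::geom_text(
        data = tibble::tibble(time = peaks$latency, gfp = peaks$amplitude,
                              label = peaks$component),
        ggplot2::aes(label = .data$label), vjust = -0.8, size = 3)
  }
  p
}

#' Plot a topographic map
#'
#' @param object an [topography()] result.
#' @param show_electrodes overlay electrode positions?
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.eeg_topography <- function(object, show_electrodes = TRUE, ...) {
  p <- ggplot2::ggplot(object$grid[!is.na(object$grid$value), ],
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "value") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (show_electrodes) {
    p <- p + ggplot2::geom_point(
      data = object$electrodes,
      ggplot2::aes(x = .data$x, y = .data$y), inherit.aes = FALSE,
      size = 0.5, colour = "black")
  }
  p
}

#' Plot per-channel reliability by cap and layout
#'
#' @param object a [channel_reliability()] table.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.reliability_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$reliability,
                               fill = .data$cap_type)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 1,
                            position = "identity", alpha = 0.6) +
    ggplot2::facet_wrap(~layout) +
    ggplot2::labs(x = "channel reliability", y = "channels") +
    ggplot2::theme_minimal()
}
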