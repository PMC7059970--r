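#' Plot methods
#'
#' `autoplot()` methods for the main result types: raster + LFP overview for
#' simulations, PSD curves with band peaks for spectral summaries, and
#' time-frequency heatmaps for spectrograms (a plain tibble from
#' [mt_spectrogram()] via [plot_spectrogram()]).
#'
#' @param object A `striatal_sim` or `spectral_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name striatr-plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname striatr-plots
#' @method autoplot striatal_sim
#' @export
autoplot.striatal_sim <- function(object, ...) {
  spikes <- object$spikes
  ggplot2::ggplot(spikes, ggplot2::aes(x = .data$time, y = .data$cell,
                                       colour = .data$population)) +
    ggplot2::geom_point(shape = "|", size = 1.5) +
    ggplot2::geom_vline(xintercept = object$settings$t_transient,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "time (ms)", y = "cell",
                  title = paste0(object$condition$label, " dopamine, ",
                                 object$populations)) +
    ggplot2::theme_minimal()
}

#' @rdname striatr-plots
#' @method autoplot spectral_summary
#' @export
autoplot.spectral_summary <- function(object, ...) {
  pk <- object$peaks[!is.na(object$peaks$peak_frequency), ]
  ggplot2::ggplot(object$psd, ggplot2::aes(x = .data$frequency, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pk,
                        ggplot2::aes(x = .data$peak_frequency, y = .data$peak_power,
                                     colour = .data$band), size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::coord_cartesian(xlim = c(0, 120)) +
    ggplot2::labs(x = "frequency (Hz)", y = "power density") +
    ggplot2::theme_minimal()
}

#' @rdname striatr-plots
#' @param spectrogram A tibble from [mt_spectrogram()].
#' @param f_max Upper frequency limit for display (Hz).
#' @export
plot_spectrogram <- function(spectrogram, f_max = 120) {
  ggplot2::ggplot(dplyr::filter(spectrogram, .data$frequency <= f_max),
                  ggplot2::aes(x = .data$time, y = .data$frequency,
                               fill = log10(.data$power + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log10 power") +
    ggplot2::labs(x = "time (ms)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}
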