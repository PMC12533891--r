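# Plotting helpers (ggplot2).

#' Plot a magnitude spectrogram
#'
#' dB-scaled tile plot of a `spectrogram`.
#'
#' @param spec A `spectrogram` from [stft_magnitude()].
#' @param db_floor Dynamic-range floor in dB below the peak (default 80).
#' @return A ggplot object.
#' @export
plot_spectrogram <- function(spec, db_floor = 80) {
  stopifnot(inherits(spec, "spectrogram"))
  m <- spec$magnitude
  db <- 20 * log10(pmax(m, max(m) * 10^(-db_floor / 20 - 1)))
  db <- pmax(db - max(db), -db_floor)
  d <- expand.grid(freq = spec$bin_freqs, time = spec$frame_times)
  d$db <- as.vector(db)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$freq, fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot per-frame ACI values
#'
#' @param series An `aci_series`.
#' @return A ggplot object.
#' @export
plot_aci_series <- function(series) {
  stopifnot(inherits(series, "aci_series"))
  d <- tidy.aci_series(series)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line(color = "#5e3c99") +
    ggplot2::geom_hline(yintercept = series$aggregate, linetype = 2) +
    ggplot2::labs(x = "frame / clump", y = sprintf("%s ACI", series$index_kind)) +
    ggplot2::theme_minimal()
}
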