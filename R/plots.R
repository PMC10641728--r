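#' Plot a comparison table as mean +/- SEM bars
#'
#' One panel per feature, one bar per group, error bars at +/- 1 SEM —
#' the standard summary figure for qEEG group tables.
#'
#' @param object A `qeeg_comparison` from [summarize_groups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qeeg_comparison
#' @export
autoplot.qeeg_comparison <- function(object, ...) {
  long <- tidy.qeeg_comparison(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$mean,
                                     fill = .data$label)) +
    ggplot2::geom_col(width = 0.7, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "mean ± SEM") +
    ggplot2::theme_minimal()
}

#' Plot a few seconds of a multichannel recording
#'
#' @param object An [eeg_recording()].
#' @param seconds Time window to draw from the start (default 10 s).
#' @param ... Unused.
#' @return A ggplot object with one facet per channel.
#' @method autoplot eeg_recording
#' @export
autoplot.eeg_recording <- function(object, seconds = 10, ...) {
  n <- min(n_samples(object), round(seconds * object$fs))
  df <- purrr::map_dfr(seq_len(nrow(object$samples)), function(ch) {
    tibble::tibble(channel = object$channel_labels[ch],
                   t = (seq_len(n) - 1) / object$fs,
                   uv = object$samples[ch, seq_len(n)])
  })
  df$channel <- factor(df$channel, levels = object$channel_labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$uv)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "µV") +
    ggplot2::theme_minimal()
}

#' Plot an epoch-averaged power spectrum
#'
#' @param object A `qeeg_psd` from [power_spectrum()].
#' @param log_y Log-scale the power axis (default TRUE).
#' @param ... Unused.
#' @return A ggplot object, one line per channel.
#' @method autoplot qeeg_psd
#' @export
autoplot.qeeg_psd <- function(object, log_y = TRUE, ...) {
  df <- purrr::map_dfr(seq_len(nrow(object$power)), function(ch) {
    tibble::tibble(channel = object$channel_labels[ch],
                   freq = object$freqs, power = object$power[ch, ])
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power,
                                        colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "frequency (Hz)", y = "power (µV²/Hz)") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @export
plot.qeeg_comparison <- function(x, ...) print(autoplot.qeeg_comparison(x, ...))
#' @export
plot.eeg_recording <- function(x, ...) print(autoplot.eeg_recording(x, ...))
#' @export
plot.qeeg_psd <- function(x, ...) print(autoplot.qeeg_psd(x, ...))
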