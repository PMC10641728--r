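#' Zero-phase band-pass filter
#'
#' Filters every channel with a zero-phase frequency-sampling filter: unit
#' gain inside `[low_hz, high_hz]`, raised-cosine transitions of width
#' `transition_hz` outside it, zero gain beyond (including DC, so any
#' constant offset is removed exactly). Zero-phase filtering preserves the
#' waveform timing that envelope-based features (aEEG) depend on, the
#' passband is exactly flat — in-band amplitudes are preserved, which keeps
#' band powers near the cutoff unbiased — and the filter is idempotent on
#' already band-limited signals.
#'
#' @param recording An [eeg_recording()].
#' @param low_hz,high_hz Passband edges in Hz; the clinical qEEG default is
#'   0.5-40 Hz.
#' @param transition_hz Widths of the lower and upper transition bands in
#'   Hz (gain falls from 1 to 0 across them).
#' @return A filtered [eeg_recording()].
#' @examples
#' rec <- synthesize_recording(make_band_profile(c(1, 0, 0, 0)),
#'                             duration_s = 8, fs = 256, seed = 1)
#' filt <- bandpass(rec)
#' @export
bandpass <- function(recording, low_hz = 0.5, high_hz = 40,
                     transition_hz = c(0.25, 4)) {
  assert_that(low_hz > 0 && low_hz < high_hz, "need 0 < low_hz < high_hz")
  assert_that(high_hz < recording$fs / 2, "high_hz must be below Nyquist")
  n <- n_samples(recording)
  fs <- recording$fs
  freqs <- (0:(n - 1)) / n * fs
  f <- pmin(freqs, fs - freqs)
  gain <- fft_bandpass_gain(f, low_hz, high_hz, transition_hz)
  out <- recording
  out$samples <- t(apply(recording$samples, 1, function(x) {
    Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
  }))
  rownames(out$samples) <- recording$channel_labels
  out
}

# Raised-cosine band-pass gain evaluated at |f|.
fft_bandpass_gain <- function(f, low, high, transition = c(0.25, 4)) {
  t_lo <- transition[1]; t_hi <- transition[2]
  gain <- numeric(length(f))
  inside <- f >= low & f <= high
  gain[inside] <- 1
  rise <- f < low & f > low - t_lo & f > 0
  gain[rise] <- 0.5 * (1 + cos(pi * (low - f[rise]) / t_lo))
  fall <- f > high & f < high + t_hi
  gain[fall] <- 0.5 * (1 + cos(pi * (f[fall] - high) / t_hi))
  gain[f == 0] <- 0
  gain
}

#' Segment a recording into fixed-length epochs
#'
#' Epochs are half-open `[start, start + L)` windows in samples; a partial
#' final epoch is dropped. With overlap `O` and length `L` over a
#' recording of duration `T`, the epoch count is
#' `floor((T - L) / (L - O)) + 1`.
#'
#' @param recording An [eeg_recording()].
#' @param epoch_length_s Epoch length in seconds.
#' @param overlap_s Overlap between consecutive epochs in seconds.
#' @return An `epoched_recording`: an `epochs` array (epoch x channel x
#'   time), the sampling rate, and a per-epoch rejection tibble
#'   (initialized to all-retained).
#' @export
segment_epochs <- function(recording, epoch_length_s = 4, overlap_s = 0) {
  fs <- recording$fs
  L <- round(epoch_length_s * fs)
  O <- round(overlap_s * fs)
  n <- n_samples(recording)
  assert_that(L <= n, sprintf(
    "recording (%.2f s) is shorter than one %.2f s epoch", n / fs, epoch_length_s))
  assert_that(O < L, "overlap must be smaller than the epoch length")
  step <- L - O
  n_epochs <- floor((n - L) / step) + 1
  epochs <- array(0, dim = c(n_epochs, nrow(recording$samples), L))
  for (e in seq_len(n_epochs)) {
    idx <- ((e - 1) * step + 1):((e - 1) * step + L)
    epochs[e, , ] <- recording$samples[, idx, drop = FALSE]
  }
  structure(
    list(epochs = epochs, fs = fs, epoch_length_s = L / fs,
         channel_labels = recording$channel_labels,
         rejection = tibble::tibble(epoch = seq_len(n_epochs),
                                    rejected = FALSE, reason = "ok")),
    class = "epoched_recording"
  )
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat(sprintf("<epoched_recording> %d epochs x %d channels x %.2f s @ %g Hz (%d retained)\n",
              dim(x$epochs)[1], dim(x$epochs)[2], x$epoch_length_s, x$fs,
              sum(!x$rejection$rejected)))
  invisible(x)
}

#' Mask artifact-contaminated epochs
#'
#' Marks epochs whose peak-to-peak amplitude on any channel exceeds
#' `peak_to_peak_limit_uv` (reason `"amplitude"` — movement, electrode pop,
#' ICU interference) or whose peak-to-peak amplitude is below
#' `flatline_limit_uv` on every channel (reason `"flatline"` — detached
#' lead). Sample values are never modified; rejection is mask-only.
#'
#' @param epoched An `epoched_recording`.
#' @param peak_to_peak_limit_uv Upper peak-to-peak limit in uV.
#' @param flatline_limit_uv Lower peak-to-peak limit in uV.
#' @return The `epoched_recording` with an updated rejection mask.
#' @export
reject_artifacts <- function(epoched, peak_to_peak_limit_uv = 200,
                             flatline_limit_uv = 0.1) {
  assert_that(peak_to_peak_limit_uv > 0 && flatline_limit_uv > 0,
              "rejection limits must be > 0")
  n_epochs <- dim(epoched$epochs)[1]
  rej <- epoched$rejection
  for (e in seq_len(n_epochs)) {
    mat <- matrix(epoched$epochs[e, , ], nrow = dim(epoched$epochs)[2])
    p2p <- apply(mat, 1, function(x) diff(range(x)))
    if (any(p2p > peak_to_peak_limit_uv)) {
      rej$rejected[e] <- TRUE; rej$reason[e] <- "amplitude"
    } else if (all(p2p < flatline_limit_uv)) {
      rej$rejected[e] <- TRUE; rej$reason[e] <- "flatline"
    }
  }
  if (all(rej$rejected)) {
    stop("all epochs were rejected; review the artifact thresholds against the data",
         call. = FALSE)
  }
  epoched$rejection <- rej
  epoched
}
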