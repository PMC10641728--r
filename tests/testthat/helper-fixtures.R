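# Shared fixtures: reference-arm profiles and simple deterministic signals.

delirium_fractions <- function() {
  fr <- c(80.29, 9.85, 6.42, 3.447)
  fr / sum(fr)
}

noncardiac_fractions <- function() {
  fr <- c(58.49, 11.64, 17.27, 12.61)
  fr / sum(fr)
}

cardiac_fractions <- function() {
  fr <- c(74.95, 9.85, 10.23, 4.97)
  fr / sum(fr)
}

# single-frequency test recording (deterministic)
sine_recording <- function(freq_hz = 10, amp_uv = 1, duration_s = 60, fs = 256,
                           n_channels = 2) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  x <- amp_uv * sin(2 * pi * freq_hz * t)
  eeg_recording(matrix(rep(x, each = n_channels), nrow = n_channels, byrow = FALSE),
                fs = fs, channel_labels = paste0("ch", seq_len(n_channels)))
}

white_recording <- function(duration_s = 60, fs = 256, n_channels = 4,
                            sd_uv = 5, seed = 99) {
  set.seed(seed)
  eeg_recording(matrix(stats::rnorm(n_channels * duration_s * fs, sd = sd_uv),
                       nrow = n_channels),
                fs = fs, channel_labels = paste0("ch", seq_len(n_channels)))
}

# a feature config that accepts arbitrary channel names
open_config <- function(rec, ...) {
  feature_config(channels = rec$channel_labels, ...)
}
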