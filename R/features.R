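#' Feature-definition configuration
#'
#' Central place for every constant the qEEG feature chain depends on, so
#' unstated algorithmic choices (band edges, entropy range, aEEG envelope
#' constants, epoch length) are explicit and adjustable.
#'
#' @param channels Channel labels a recording must provide.
#' @param bandpass Analysis band-pass in Hz applied before all features.
#' @param epoch_length_s,epoch_overlap_s Epoch segmentation for the PSD.
#' @param peak_to_peak_limit_uv,flatline_limit_uv Artifact-rejection limits.
#' @param band_edges,band_names Relative-power band definition
#'   (delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30 Hz by convention).
#' @param normalization_range Range the band fractions are normalized over.
#' @param se_range Range of the spectral-entropy computation.
#' @param sef_quantile,sef_range Spectral-edge quantile (0.95) and range.
#' @param rav_numerator,rav_denominator RAV band ratio ranges (6-14 Hz over
#'   1-20 Hz).
#' @param rav_window_s RAV analysis window; when the recording is longer,
#'   RAV uses its first `rav_window_s` seconds (120 s by convention).
#' @param aeeg_band aEEG asymmetric filter passband in Hz.
#' @param aeeg_gain_exponent,aeeg_gain_ref_hz The aEEG rising frequency
#'   response is approximated by the fixed gain curve
#'   `(f / ref)^exponent` inside `aeeg_band` (0.6 amplitude exponent =
#'   12 dB/decade, unity at 9 Hz).
#' @param aeeg_window_s Peak-to-peak envelope window in seconds.
#' @param aeeg_smooth_s Envelope moving-average smoothing span in seconds.
#' @param aeeg_percentiles Envelope percentiles reported as the lower and
#'   upper aEEG border amplitudes.
#' @return A `qeeg_config` list.
#' @export
feature_config <- function(channels = default_channels(),
                           bandpass = c(0.5, 40),
                           epoch_length_s = 8,
                           epoch_overlap_s = 4,
                           peak_to_peak_limit_uv = 200,
                           flatline_limit_uv = 0.1,
                           band_edges = c(0.5, 4, 8, 13, 30),
                           band_names = c("delta", "theta", "alpha", "beta"),
                           normalization_range = c(0.5, 30),
                           se_range = c(0.5, 40),
                           sef_quantile = 0.95,
                           sef_range = c(0.5, 40),
                           rav_numerator = c(6, 14),
                           rav_denominator = c(1, 20),
                           rav_window_s = 120,
                           aeeg_band = c(2, 15),
                           aeeg_gain_exponent = 0.6,
                           aeeg_gain_ref_hz = 9,
                           aeeg_window_s = 0.5,
                           aeeg_smooth_s = 15,
                           aeeg_percentiles = c(0.1, 0.9)) {
  structure(as.list(environment()), class = "qeeg_config")
}

#' Epoch-averaged power spectral density
#'
#' Hann-tapered periodogram of every retained epoch, averaged across epochs
#' per channel. The taper is power-normalized so the integral of the PSD
#' over the one-sided grid matches the signal variance (Parseval), and the
#' grid resolution is the reciprocal epoch length — 0.125 Hz at the default
#' 8 s epochs (each epoch is a single tapered window; the fine resolution
#' keeps spectral-leakage bias at the 1 Hz-edged clinical band boundaries
#' small, and the default 50% epoch overlap recovers the variance lost to
#' the taper).
#'
#' @param epoched An `epoched_recording` from [segment_epochs()] (possibly
#'   after [reject_artifacts()]).
#' @return A `qeeg_psd`: frequency grid, channels x frequency power matrix
#'   in uV^2/Hz, resolution and the number of epochs used.
#' @export
power_spectrum <- function(epoched) {
  keep <- which(!epoched$rejection$rejected)
  assert_that(length(keep) >= 1, "no retained epochs to estimate a spectrum from")
  fs <- epoched$fs
  L <- dim(epoched$epochs)[3]
  nch <- dim(epoched$epochs)[2]
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann taper
  u <- sum(w^2)                                        # power normalization
  n_freq <- floor(L / 2) + 1
  freqs <- (seq_len(n_freq) - 1) * fs / L
  power <- matrix(0, nrow = nch, ncol = n_freq)
  for (e in keep) {
    mat <- matrix(epoched$epochs[e, , ], nrow = nch)
    for (ch in seq_len(nch)) {
      spec <- abs(stats::fft(mat[ch, ] * w))^2 / (fs * u)
      p <- spec[seq_len(n_freq)]
      # one-sided: double everything except DC (and Nyquist when L is even)
      two <- 2:(n_freq - if (L %% 2 == 0) 1 else 0)
      p[two] <- 2 * p[two]
      power[ch, ] <- power[ch, ] + p
    }
  }
  power <- power / length(keep)
  structure(
    list(freqs = freqs, power = power, fs = fs, resolution_hz = fs / L,
         n_epochs_used = length(keep), channel_labels = epoched$channel_labels),
    class = "qeeg_psd"
  )
}

#' Construct a PSD object directly
#'
#' Mainly for analytic checks: wraps an explicit frequency grid and power
#' matrix in the `qeeg_psd` container the feature functions consume.
#'
#' @param freqs Strictly increasing Hz grid.
#' @param power Channels x frequency matrix (or a vector for one channel),
#'   uV^2/Hz, nonnegative.
#' @param channel_labels Optional labels.
#' @return A `qeeg_psd`.
#' @export
as_qeeg_psd <- function(freqs, power, channel_labels = NULL) {
  if (is.vector(power)) power <- matrix(power, nrow = 1)
  assert_that(all(diff(freqs) > 0), "freqs must be strictly increasing")
  assert_that(all(power >= 0), "power must be nonnegative")
  assert_that(ncol(power) == length(freqs), "power needs one column per frequency")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(power)))
  structure(
    list(freqs = freqs, power = power, fs = NA_real_,
         resolution_hz = stats::median(diff(freqs)),
         n_epochs_used = NA_integer_, channel_labels = channel_labels),
    class = "qeeg_psd"
  )
}

#' @export
print.qeeg_psd <- function(x, ...) {
  cat(sprintf("<qeeg_psd> %d channels, %.3g-%.3g Hz @ %.3g Hz resolution (%s epochs)\n",
              nrow(x$power), min(x$freqs), max(x$freqs), x$resolution_hz,
              x$n_epochs_used))
  invisible(x)
}

channel_mean <- function(v) mean(v)

#' Relative band powers
#'
#' Per channel, the trapezoidal integral of the PSD over each band divided
#' by the integral over the normalization range, in percent; then averaged
#' across channels (unless `by_channel`).
#'
#' @param psd A `qeeg_psd`.
#' @param band_edges,band_names,normalization_range See [feature_config()].
#' @param by_channel Return the per-channel table instead of the channel
#'   mean.
#' @return A tibble with `band` and `pct` (plus `channel` when
#'   `by_channel = TRUE`).
#' @export
relative_band_powers <- function(psd, band_edges = c(0.5, 4, 8, 13, 30),
                                 band_names = c("delta", "theta", "alpha", "beta"),
                                 normalization_range = c(0.5, 30),
                                 by_channel = FALSE) {
  assert_that(band_edges[1] >= psd$freqs[1] - 1e-9 &&
                band_edges[length(band_edges)] <= psd$freqs[length(psd$freqs)] + 1e-9,
              "bands must lie inside the PSD grid")
  nb <- length(band_edges) - 1
  per_ch <- purrr::map_dfr(seq_len(nrow(psd$power)), function(ch) {
    y <- psd$power[ch, ]
    tot <- trapz_range(psd$freqs, y, normalization_range[1], normalization_range[2])
    assert_that(tot > 0, "zero total power in the normalization range")
    tibble::tibble(
      channel = psd$channel_labels[ch],
      band = band_names,
      pct = vapply(seq_len(nb), function(j) {
        100 * trapz_range(psd$freqs, y, band_edges[j], band_edges[j + 1]) / tot
      }, numeric(1))
    )
  })
  if (by_channel) return(per_ch)
  per_ch |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(pct = mean(.data$pct), .groups = "drop") |>
    dplyr::arrange(match(.data$band, band_names))
}

#' Spectral entropy (0-100)
#'
#' Shannon entropy of the PSD normalized over `range`, divided by the log
#' of the number of bins in the range and scaled to 0-100; computed per
#' channel and averaged. 100 corresponds to a flat (white) spectrum, values
#' near 0 to a single spectral line; sedation lowers it.
#'
#' @param psd A `qeeg_psd`.
#' @param range Hz range, default 0.5-40.
#' @param by_channel Return per-channel values.
#' @return Scalar SE (or named vector).
#' @export
spectral_entropy <- function(psd, range = c(0.5, 40), by_channel = FALSE) {
  sel <- psd$freqs >= range[1] & psd$freqs <= range[2]
  assert_that(sum(sel) >= 2, "spectral entropy needs at least two bins in range")
  per_ch <- apply(psd$power[, sel, drop = FALSE], 1, function(y) {
    tot <- sum(y)
    assert_that(tot > 0, "zero power in the spectral-entropy range")
    p <- y / tot
    p <- p[p > 0]
    100 * (-sum(p * log(p))) / log(sum(sel))
  })
  names(per_ch) <- psd$channel_labels
  if (by_channel) per_ch else mean(per_ch)
}

#' Spectral edge frequency
#'
#' Smallest frequency below which `quantile` of the power within `range`
#' lies, with linear interpolation of the cumulative trapezoidal integral
#' between grid points (removing grid-resolution bias); per channel, then
#' averaged.
#'
#' @param psd A `qeeg_psd`.
#' @param quantile Power quantile, default 0.95 (SEF95).
#' @param range Hz range, default 0.5-40.
#' @param by_channel Return per-channel values.
#' @return Hz.
#' @export
spectral_edge_frequency <- function(psd, quantile = 0.95, range = c(0.5, 40),
                                    by_channel = FALSE) {
  lo <- max(range[1], psd$freqs[1]); hi <- min(range[2], psd$freqs[length(psd$freqs)])
  per_ch <- apply(psd$power, 1, function(y) {
    keep <- psd$freqs > lo & psd$freqs < hi
    xs <- c(lo, psd$freqs[keep], hi)
    ys <- c(stats::approx(psd$freqs, y, lo)$y, y[keep],
            stats::approx(psd$freqs, y, hi)$y)
    cum <- cumtrapz(xs, ys)
    tot <- cum[length(cum)]
    assert_that(tot > 0, "zero power in the spectral-edge range")
    target <- quantile * tot
    i <- which(cum >= target - 1e-15)[1]
    if (i <= 1) return(xs[1])
    # linear interpolation within the segment that crosses the target
    frac <- (target - cum[i - 1]) / (cum[i] - cum[i - 1])
    xs[i - 1] + frac * (xs[i] - xs[i - 1])
  })
  names(per_ch) <- psd$channel_labels
  if (by_channel) per_ch else mean(per_ch)
}

#' Relative alpha variability (band-ratio definition)
#'
#' 100 x (6-14 Hz power) / (1-20 Hz power), per channel then averaged —
#' the band-ratio definition used for sedated ICU recordings as a cerebral
#' blood flow correlate (a time-course variability definition is a
#' different quantity and is not implemented).
#'
#' @param psd A `qeeg_psd`; its grid must cover the denominator range.
#' @param numerator,denominator Hz ranges.
#' @param by_channel Return per-channel values.
#' @return Percent.
#' @export
relative_alpha_variability <- function(psd, numerator = c(6, 14),
                                       denominator = c(1, 20),
                                       by_channel = FALSE) {
  assert_that(psd$freqs[1] <= denominator[1] &&
                psd$freqs[length(psd$freqs)] >= denominator[2],
              "PSD grid must cover the RAV denominator range")
  per_ch <- apply(psd$power, 1, function(y) {
    den <- trapz_range(psd$freqs, y, denominator[1], denominator[2])
    assert_that(den > 0, "zero power in the RAV denominator range")
    100 * trapz_range(psd$freqs, y, numerator[1], numerator[2]) / den
  })
  names(per_ch) <- psd$channel_labels
  if (by_channel) per_ch else mean(per_ch)
}

#' Amplitude-integrated EEG border amplitudes
#'
#' Classic aEEG chain on each channel: band-pass 2-15 Hz with the rising
#' frequency response approximated by the fixed gain curve
#' `(f / 9)^0.6` (about 12 dB/decade), peak-to-peak envelope over 0.5 s
#' windows, moving-average smoothing over 15 s, and the 10th / 90th
#' percentiles of the smoothed envelope as the lower and upper border
#' amplitudes; channel-averaged. A stationary sinusoid of amplitude A at
#' frequency f maps to an envelope of `2 A gain(f)`.
#'
#' @param recording An [eeg_recording()] of at least 30 s.
#' @param config A [feature_config()] carrying the aEEG constants.
#' @param by_channel Return the per-channel tibble.
#' @return A one-row tibble with `lower_uv` and `upper_uv` (channel means),
#'   or a per-channel tibble when `by_channel = TRUE`.
#' @export
aeeg_limits <- function(recording, config = feature_config(), by_channel = FALSE) {
  assert_that(duration_s(recording) >= 30,
              "aEEG limits need a recording of at least 30 s")
  fs <- recording$fs
  n <- n_samples(recording)
  freqs <- (0:(n - 1)) / n * fs
  f <- pmin(freqs, fs - freqs)
  gain <- fft_bandpass_gain(f, config$aeeg_band[1], config$aeeg_band[2],
                            transition = c(0.5, 2))
  shaped <- ifelse(f > 0, (f / config$aeeg_gain_ref_hz)^config$aeeg_gain_exponent, 0)
  gain <- gain * shaped
  win <- round(config$aeeg_window_s * fs)
  smooth_n <- max(1, round(config$aeeg_smooth_s / config$aeeg_window_s))
  per_ch <- purrr::map_dfr(seq_len(nrow(recording$samples)), function(ch) {
    x <- Re(stats::fft(stats::fft(recording$samples[ch, ]) * gain, inverse = TRUE)) / n
    n_win <- floor(length(x) / win)
    env <- vapply(seq_len(n_win), function(wi) {
      seg <- x[((wi - 1) * win + 1):(wi * win)]
      diff(range(seg))
    }, numeric(1))
    env_s <- moving_average(env, smooth_n)
    qs <- stats::quantile(env_s, probs = config$aeeg_percentiles, names = FALSE)
    tibble::tibble(channel = recording$channel_labels[ch],
                   lower_uv = qs[1], upper_uv = qs[2])
  })
  if (by_channel) return(per_ch)
  tibble::tibble(lower_uv = mean(per_ch$lower_uv), upper_uv = mean(per_ch$upper_uv))
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, width) {
  if (width <= 1 || length(x) <= 1) return(x)
  half <- floor(width / 2)
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Extract the full qEEG feature set from a recording
#'
#' Runs the complete chain — analysis band-pass, epoch segmentation,
#' artifact masking, epoch-averaged PSD — and computes spectral entropy,
#' aEEG border amplitudes, relative alpha variability, the four relative
#' band powers and SEF95, per channel and as the all-channel average.
#' Deterministic given the input.
#'
#' @param recording An [eeg_recording()] containing at least the channels
#'   named in `config$channels`.
#' @param config A [feature_config()].
#' @return A `qeeg_features` tibble: one row per channel plus a `"mean"`
#'   row, with columns `se`, `aeeg_upper_uv`, `aeeg_lower_uv`,
#'   `rav_pct`, `delta_pct`, `theta_pct`, `alpha_pct`, `beta_pct`,
#'   `sef95_hz`; subject metadata in attributes `subject_id` and
#'   `group_label`.
#' @examples
#' prof <- make_band_profile(c(0.8, 0.1, 0.06, 0.04))
#' rec <- synthesize_recording(prof, duration_s = 40, fs = 256, seed = 2)
#' extract_features(rec)
#' @export
extract_features <- function(recording, config = feature_config()) {
  missing <- setdiff(config$channels, recording$channel_labels)
  assert_that(length(missing) == 0,
              paste("recording is missing required channels:",
                    paste(missing, collapse = ", ")))
  # restrict to the configured channels, in configured order
  rec <- recording
  rec$samples <- recording$samples[config$channels, , drop = FALSE]
  rec$channel_labels <- config$channels

  filt <- bandpass(rec, config$bandpass[1], config$bandpass[2])
  ep <- segment_epochs(filt, config$epoch_length_s, config$epoch_overlap_s)
  ep <- reject_artifacts(ep, config$peak_to_peak_limit_uv, config$flatline_limit_uv)
  psd <- power_spectrum(ep)

  # RAV is defined over a fixed-length analysis window (first rav_window_s)
  psd_rav <- psd
  if (duration_s(filt) > config$rav_window_s + 1e-9) {
    short <- filt
    short$samples <- filt$samples[, seq_len(round(config$rav_window_s * filt$fs)),
                                  drop = FALSE]
    ep2 <- segment_epochs(short, config$epoch_length_s, config$epoch_overlap_s)
    ep2 <- reject_artifacts(ep2, config$peak_to_peak_limit_uv, config$flatline_limit_uv)
    psd_rav <- power_spectrum(ep2)
  }

  se <- spectral_entropy(psd, config$se_range, by_channel = TRUE)
  sef <- spectral_edge_frequency(psd, config$sef_quantile, config$sef_range,
                                 by_channel = TRUE)
  rav <- relative_alpha_variability(psd_rav, config$rav_numerator,
                                    config$rav_denominator, by_channel = TRUE)
  bands <- relative_band_powers(psd, config$band_edges, config$band_names,
                                config$normalization_range, by_channel = TRUE)
  bands_w <- tidyr::pivot_wider(bands, names_from = "band", values_from = "pct")
  ae <- aeeg_limits(filt, config, by_channel = TRUE)

  per_ch <- tibble::tibble(channel = config$channels) |>
    dplyr::left_join(tibble::tibble(channel = names(se), se = unname(se)), by = "channel") |>
    dplyr::left_join(ae, by = "channel") |>
    dplyr::left_join(tibble::tibble(channel = names(rav), rav_pct = unname(rav)), by = "channel") |>
    dplyr::left_join(bands_w, by = "channel") |>
    dplyr::left_join(tibble::tibble(channel = names(sef), sef95_hz = unname(sef)), by = "channel") |>
    dplyr::rename(aeeg_upper_uv = "upper_uv", aeeg_lower_uv = "lower_uv") |>
    dplyr::select("channel", "se", "aeeg_upper_uv", "aeeg_lower_uv", "rav_pct",
                  dplyr::all_of(paste0(config$band_names, "")), "sef95_hz")
  names(per_ch)[names(per_ch) %in% config$band_names] <-
    paste0(config$band_names, "_pct")
  mean_row <- per_ch |>
    dplyr::summarise(dplyr::across(-"channel", mean)) |>
    dplyr::mutate(channel = "mean", .before = 1)
  out <- dplyr::bind_rows(per_ch, mean_row)
  structure(out, subject_id = recording$subject_id,
            group_label = recording$group_label,
            class = c("qeeg_features", class(out)))
}

#' Extract features for every recording in a cohort
#'
#' @param cohort A list of [eeg_recording()]s (e.g. from
#'   [synthesize_cohort()]).
#' @param config A [feature_config()].
#' @return A tibble with one row per subject (the channel-averaged feature
#'   values) and columns `subject_id`, `group_label`, then the features.
#' @export
cohort_features <- function(cohort, config = feature_config()) {
  purrr::map_dfr(cohort, function(rec) {
    ft <- extract_features(rec, config)
    dplyr::filter(ft, .data$channel == "mean") |>
      dplyr::select(-"channel") |>
      dplyr::mutate(subject_id = attr(ft, "subject_id"),
                    group_label = attr(ft, "group_label"),
                    .before = 1)
  })
}
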