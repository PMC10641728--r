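#' Multichannel EEG recordings
#'
#' An `eeg_recording` holds a channels x time matrix in microvolts together
#' with its sampling rate and channel labels. The default montage is the
#' eight referential 10/20 channels used for wearable ICU recordings:
#' Fp1, Fp2, C3, C4, T3, T4, O1, O2.
#'
#' @param samples Numeric matrix, channels x time, in uV.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Unique channel names, one per row.
#' @param start_time Start timestamp (informational).
#' @param subject_id,group_label Optional subject metadata.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_labels = rownames(samples),
                          start_time = "2000-01-01 00:00:00",
                          subject_id = NA_character_, group_label = NA_character_) {
  samples <- as.matrix(samples)
  assert_that(fs > 0, "fs must be > 0")
  assert_that(!is.null(channel_labels) && length(channel_labels) == nrow(samples),
              "need one channel label per row of samples")
  assert_that(!anyDuplicated(channel_labels), "channel labels must be unique")
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = fs, channel_labels = as.character(channel_labels),
         start_time = start_time, subject_id = subject_id, group_label = group_label),
    class = "eeg_recording"
  )
}

#' Standard 8-channel ICU montage labels
#' @return Character vector of 10/20 channel names.
#' @export
default_channels <- function() c("Fp1", "Fp2", "C3", "C4", "T3", "T4", "O1", "O2")

n_samples <- function(rec) ncol(rec$samples)
duration_s <- function(rec) ncol(rec$samples) / rec$fs

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$samples), ncol(x$samples), duration_s(x), x$fs))
  cat("  channels: ", paste(x$channel_labels, collapse = ", "), "\n", sep = "")
  if (!is.na(x$subject_id)) cat("  subject:  ", x$subject_id, "\n", sep = "")
  if (!is.na(x$group_label)) cat("  group:    ", x$group_label, "\n", sep = "")
  invisible(x)
}

#' Synthesize one EEG recording from a spectral profile
#'
#' Builds each channel as a sum of independent band-limited Gaussian noise
#' components, one per profile segment (the four bands plus the sub-delta
#' slot when present). Each component is white noise shaped in the
#' frequency domain by the square root of the segment's target density — a
#' zero-phase brick-wall filter, so there is no inter-band leakage and no
#' passband ripple — and then rescaled so its realized power over the whole
#' recording equals the segment's share exactly. Because the components
#' occupy disjoint frequency supports they are exactly orthogonal, and the
#' recording's total RMS equals `amplitude_scale` exactly. Channels use
#' independent noise draws from a single seeded stream, so the same seed
#' reproduces the recording bit for bit.
#'
#' @inheritParams calibrate_profile
#' @param duration_s Recording length in seconds (>= 4).
#' @param fs Sampling rate in Hz (>= 128; must exceed twice the highest
#'   band edge).
#' @param channel_labels Channel names; default the 8-channel ICU montage.
#' @param seed Integer seed; identical seeds give identical recordings.
#' @param subject_id,group_label Metadata carried on the recording.
#' @return An [eeg_recording()].
#' @examples
#' prof <- make_band_profile(c(0.8, 0.1, 0.06, 0.04))
#' rec <- synthesize_recording(prof, duration_s = 8, fs = 256, seed = 1)
#' @export
synthesize_recording <- function(profile, duration_s = 120, fs = 256,
                                 channel_labels = default_channels(), seed = 1L,
                                 subject_id = NA_character_,
                                 group_label = NA_character_) {
  assert_that(duration_s >= 4, "duration_s must be >= 4 s")
  assert_that(fs >= 128, "fs must be >= 128 Hz")
  assert_that(fs > 2 * max(profile$band_edges),
              "fs must exceed twice the highest band edge (Nyquist)")
  n <- round(duration_s * fs)
  freqs <- (0:(n - 1)) / n * fs
  freqs_folded <- pmin(freqs, fs - freqs)  # |f| for the two-sided grid
  seg <- profile_segments(profile)
  nch <- length(channel_labels)
  target_var <- profile$amplitude_scale^2

  samples <- with_seed(seed, {
    out <- matrix(0, nrow = nch, ncol = n)
    for (ch in seq_len(nch)) {
      x <- numeric(n)
      for (k in seq_len(nrow(seg))) {
        if (seg$mass[k] <= 0) next
        sel <- freqs_folded >= seg$lo[k] & freqs_folded < seg$hi[k]
        assert_that(any(sel), sprintf(
          "no frequency bins inside %g-%g Hz at this duration; use a longer recording",
          seg$lo[k], seg$hi[k]))
        gain <- numeric(n)
        gain[sel] <- sqrt(freqs_folded[sel]^seg$tilt[k])
        z <- stats::rnorm(n)
        comp <- Re(stats::fft(stats::fft(z) * gain, inverse = TRUE)) / n
        v <- mean(comp^2)
        p_target <- seg$mass[k] * target_var
        x <- x + comp * sqrt(p_target / v)
      }
      out[ch, ] <- x
    }
    out
  })

  eeg_recording(samples, fs = fs, channel_labels = channel_labels,
                subject_id = subject_id, group_label = group_label)
}

#' Specify a synthetic cohort
#'
#' @param groups A tibble (or data frame) with one row per study arm:
#'   columns `label`, `n`, `profile` (list column of
#'   [make_band_profile()] objects) and optionally `dispersion` (list
#'   column of [profile_dispersion()] objects; defaults to no
#'   between-subject variability).
#' @param duration_s,fs Recording length and sampling rate.
#' @param channel_labels Channel names.
#' @param seed Cohort seed; per-subject seeds are derived from it with a
#'   stable integer hash, so subject `i` of group `g` is reproducible
#'   independently of generation order.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(groups, duration_s = 120, fs = 256,
                        channel_labels = default_channels(), seed = 1L) {
  groups <- tibble::as_tibble(groups)
  assert_that(all(c("label", "n", "profile") %in% names(groups)),
              "groups needs columns label, n, profile")
  assert_that(all(groups$n >= 1), "each group needs n >= 1 subjects")
  if (!"dispersion" %in% names(groups)) {
    groups$dispersion <- purrr::map(seq_len(nrow(groups)), ~profile_dispersion())
  }
  for (p in groups$profile) {
    assert_that(fs > 2 * max(p$band_edges), "fs must exceed twice the highest band edge")
  }
  structure(
    list(groups = groups, duration_s = duration_s, fs = fs,
         channel_labels = channel_labels, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Between-subject dispersion of profile parameters
#'
#' Variability is applied on scales that respect the parameter constraints:
#' logit-normal jitter on band fractions (renormalized, so they stay on the
#' simplex), log-normal on the RMS amplitude, logit-normal on the sub-delta
#' mass. All standard deviations are on the transformed scale and default
#' to zero.
#'
#' @param fractions Logit-scale SD per band (recycled).
#' @param amplitude Log-scale SD of `amplitude_scale`.
#' @param subdelta Logit-scale SD of `subdelta_mass`.
#' @return A `profile_dispersion` object.
#' @export
profile_dispersion <- function(fractions = 0, amplitude = 0, subdelta = 0) {
  assert_that(all(c(fractions, amplitude, subdelta) >= 0),
              "dispersion values must be >= 0")
  structure(list(fractions = fractions, amplitude = amplitude, subdelta = subdelta),
            class = "profile_dispersion")
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# Draw one subject's profile around a group mean (uses the current RNG).
jitter_profile <- function(profile, dispersion) {
  out <- profile
  sig <- rep_len(dispersion$fractions, length(profile$band_fractions))
  if (any(sig > 0)) {
    p <- pmin(pmax(profile$band_fractions, 1e-12), 1 - 1e-12)
    drawn <- inv_logit(logit(p) + stats::rnorm(length(p), 0, sig))
    out$band_fractions <- drawn / sum(drawn)
  }
  if (dispersion$subdelta > 0 && profile$subdelta_mass > 0) {
    m <- min(max(profile$subdelta_mass, 1e-12), 1 - 1e-12)
    out$subdelta_mass <- inv_logit(logit(m) + stats::rnorm(1, 0, dispersion$subdelta))
  }
  if (dispersion$amplitude > 0) {
    out$amplitude_scale <- profile$amplitude_scale *
      exp(stats::rnorm(1, 0, dispersion$amplitude))
  }
  out
}

#' Synthesize a whole cohort
#'
#' Draws one profile per subject around its group mean (see
#' [profile_dispersion()]) and synthesizes one recording per subject.
#' Subject seeds are derived deterministically from the cohort seed, so the
#' dataset is byte-reproducible.
#'
#' @param spec A [cohort_spec()].
#' @return A list of [eeg_recording()]s (class `eeg_cohort`) with a
#'   `manifest` attribute: a tibble with `subject_id`, `group_label`,
#'   `seed`, the drawn `amplitude_scale` and drawn band fractions.
#' @export
synthesize_cohort <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  recs <- list()
  manifest <- list()
  for (g in seq_len(nrow(spec$groups))) {
    grp <- spec$groups[g, ]
    prof0 <- grp$profile[[1]]
    disp <- grp$dispersion[[1]]
    for (i in seq_len(grp$n)) {
      sseed <- derive_seed(spec$seed, g, i)
      subj <- sprintf("%s_%02d", grp$label, i)
      prof <- with_seed(sseed, jitter_profile(prof0, disp))
      rec <- synthesize_recording(prof, duration_s = spec$duration_s, fs = spec$fs,
                                  channel_labels = spec$channel_labels,
                                  seed = sseed + 1L,
                                  subject_id = subj, group_label = grp$label)
      recs[[length(recs) + 1]] <- rec
      manifest[[length(manifest) + 1]] <- tibble::tibble(
        subject_id = subj, group_label = grp$label, seed = sseed,
        amplitude_scale = prof$amplitude_scale,
        subdelta_mass = prof$subdelta_mass,
        fractions = paste(format(prof$band_fractions, digits = 8), collapse = ";")
      )
    }
  }
  structure(recs, manifest = dplyr::bind_rows(manifest), class = "eeg_cohort")
}

#' Manifest of a synthesized cohort
#' @param cohort An `eeg_cohort` from [synthesize_cohort()].
#' @return The manifest tibble.
#' @export
cohort_manifest <- function(cohort) attr(cohort, "manifest")
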