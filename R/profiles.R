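#' Parametric EEG power-spectrum profiles
#'
#' A `spectral_profile` is the generator-side description of an EEG power
#' spectrum: relative band powers over a normalization range (the classic
#' delta/theta/alpha/beta fractions), an optional slow-delta ("sub-delta")
#' mass lying below the normalization range, a within-band power-law tilt,
#' and an overall RMS amplitude in microvolts. The profile's theoretical
#' features (band fractions, SEF95, relative alpha variability) are
#' available in closed form, which is what makes exact calibration to
#' published group means possible.
#'
#' The spectrum is piecewise: within band `j` spanning `[e_j, e_{j+1})` the
#' density is proportional to `f^tilt`, normalized so the band integrates to
#' its requested fraction of the power in the normalization range. The
#' sub-delta component rises steeply (density proportional to `f^6`) across
#' `subdelta_band` (default 0.5-1 Hz, so its mass concentrates just below
#' the delta edge) and carries a proportion `subdelta_mass` of the total
#' 0.5-40 Hz power;
#' it is counted by SEF/aEEG-style features but excluded from the band
#' fraction normalization, mirroring how slow-delta dominance in sedated
#' ICU EEG pulls the spectral edge down without changing the printed
#' delta/theta/alpha/beta split.
#'
#' @param band_fractions Nonnegative proportions of power per band; must sum
#'   to 1 within `1e-6` (renormalized exactly internally).
#' @param band_edges Strictly increasing band breakpoints in Hz, one more
#'   than the number of fractions. Default 1-4-8-13-30 Hz
#'   (delta/theta/alpha/beta).
#' @param normalization_range Two-element Hz range over which the fractions
#'   are defined; bands must lie inside it. Defaults to the span of
#'   `band_edges`.
#' @param amplitude_scale Target RMS amplitude of the synthesized signal in
#'   microvolts. The default 7 uV RMS puts the theoretical aEEG upper
#'   border in the 12-16 uV range typical of sedated adult scalp EEG.
#' @return An object of class `spectral_profile`.
#' @examples
#' prof <- make_band_profile(c(0.8029, 0.0985, 0.0642, 0.0344))
#' theoretical_sef95(prof)
#' @export
make_band_profile <- function(band_fractions,
                              band_edges = c(1, 4, 8, 13, 30),
                              normalization_range = range(band_edges),
                              amplitude_scale = 7) {
  assert_that(all(band_fractions >= 0), "band_fractions must be nonnegative")
  assert_that(length(band_edges) == length(band_fractions) + 1,
              "need one band fraction per band (length(band_edges) == length(band_fractions) + 1)")
  s <- sum(band_fractions)
  assert_that(abs(s - 1) <= 1e-6,
              sprintf("band_fractions must sum to 1 (got %.8f)", s))
  assert_that(all(diff(band_edges) > 0), "band_edges must be strictly increasing")
  assert_that(normalization_range[1] <= band_edges[1] &&
                normalization_range[2] >= band_edges[length(band_edges)],
              "bands must lie inside normalization_range")
  # sub-delta slot sits just below the normalization range (if there is room)
  sd_hi <- max(0.5, normalization_range[1])
  sd_lo <- max(0.5, sd_hi - 0.5)
  new_spectral_profile(
    band_edges = as.numeric(band_edges),
    band_fractions = as.numeric(band_fractions) / s,
    normalization_range = as.numeric(normalization_range),
    subdelta_mass = 0,
    subdelta_band = c(sd_lo, sd_hi),
    in_band_tilt = 0,
    amplitude_scale = amplitude_scale
  )
}

new_spectral_profile <- function(band_edges, band_fractions, normalization_range,
                                 subdelta_mass, subdelta_band, in_band_tilt,
                                 amplitude_scale) {
  p <- structure(
    list(
      band_edges = band_edges,
      band_fractions = band_fractions,
      normalization_range = normalization_range,
      subdelta_mass = subdelta_mass,
      subdelta_band = subdelta_band,
      in_band_tilt = in_band_tilt,
      amplitude_scale = amplitude_scale
    ),
    class = "spectral_profile"
  )
  validate_spectral_profile(p)
  p
}

validate_spectral_profile <- function(p) {
  assert_that(all(p$band_fractions >= 0) &&
                abs(sum(p$band_fractions) - 1) <= 1e-9,
              "band_fractions must be >= 0 and sum to 1 within 1e-9")
  assert_that(all(diff(p$band_edges) > 0), "band_edges must be strictly increasing")
  assert_that(p$normalization_range[1] >= 0.5 && p$normalization_range[2] <= 40,
              "normalization_range must lie within [0.5, 40] Hz")
  assert_that(p$amplitude_scale > 0, "amplitude_scale must be > 0")
  assert_that(p$subdelta_mass >= 0 && p$subdelta_mass < 1,
              "subdelta_mass must be in [0, 1)")
  if (p$subdelta_mass > 0) {
    assert_that(p$subdelta_band[1] >= 0.5 &&
                  p$subdelta_band[2] <= p$normalization_range[1] &&
                  p$subdelta_band[2] > p$subdelta_band[1],
                "subdelta_band must be a nonempty range in [0.5 Hz, normalization lower edge]")
  }
  invisible(p)
}

# ---- closed-form spectral geometry ------------------------------------------

# Integral of f^t over [a, b] (a > 0).
powlaw_integral <- function(a, b, t) {
  if (b <= a) return(0)
  if (abs(t + 1) < 1e-12) log(b / a) else (b^(t + 1) - a^(t + 1)) / (t + 1)
}

# Shape exponent of the sub-delta component: its density rises as f^6
# toward the delta edge, so essentially all of its mass sits well inside
# the 0.5-40 Hz analysis band even after spectral-estimation smoothing.
.subdelta_tilt <- 6

# Piecewise components of the unit-total-power density: one row per segment
# with lo, hi, mass and tilt.
profile_segments <- function(profile) {
  ne <- length(profile$band_edges)
  lo <- profile$band_edges[-ne]
  hi <- profile$band_edges[-1]
  m <- profile$subdelta_mass
  seg <- data.frame(
    lo = lo, hi = hi,
    mass = (1 - m) * profile$band_fractions,
    tilt = profile$in_band_tilt
  )
  if (m > 0) {
    seg <- rbind(
      data.frame(lo = profile$subdelta_band[1], hi = profile$subdelta_band[2],
                 mass = m, tilt = .subdelta_tilt),
      seg
    )
  }
  seg
}

# Total profile power within [lo, hi], as a proportion of the unit total.
profile_power_in <- function(profile, lo, hi) {
  seg <- profile_segments(profile)
  tot <- 0
  for (k in seq_len(nrow(seg))) {
    a <- max(seg$lo[k], lo); b <- min(seg$hi[k], hi)
    if (b > a && seg$mass[k] > 0) {
      tot <- tot + seg$mass[k] *
        powlaw_integral(a, b, seg$tilt[k]) /
        powlaw_integral(seg$lo[k], seg$hi[k], seg$tilt[k])
    }
  }
  tot
}

#' Theoretical spectral density of a profile
#'
#' Evaluates the profile's power spectral density (uV^2/Hz) on a frequency
#' grid; integrates to `amplitude_scale^2` over 0.5-40 Hz.
#'
#' @param profile A [make_band_profile()] object.
#' @param freqs Frequencies in Hz.
#' @return Numeric vector of densities.
#' @export
profile_density <- function(profile, freqs) {
  seg <- profile_segments(profile)
  d <- numeric(length(freqs))
  for (k in seq_len(nrow(seg))) {
    inside <- freqs >= seg$lo[k] & freqs < seg$hi[k]
    if (any(inside) && seg$mass[k] > 0) {
      d[inside] <- d[inside] + seg$mass[k] * freqs[inside]^seg$tilt[k] /
        powlaw_integral(seg$lo[k], seg$hi[k], seg$tilt[k])
    }
  }
  d * profile$amplitude_scale^2
}

#' Theoretical band fractions of a profile
#'
#' Closed-form relative band powers (percent) as a feature extractor with
#' the given band definition would see them on the exact spectrum.
#'
#' @inheritParams profile_density
#' @param band_edges Band breakpoints in Hz used by the extractor.
#' @param normalization_range Range over which fractions are normalized.
#' @return Tibble with `band`, `lo`, `hi`, `pct`.
#' @export
theoretical_band_fractions <- function(profile,
                                       band_edges = profile$band_edges,
                                       normalization_range = profile$normalization_range) {
  tot <- profile_power_in(profile, normalization_range[1], normalization_range[2])
  assert_that(tot > 0, "profile has no power in the normalization range")
  nb <- length(band_edges) - 1
  pct <- vapply(seq_len(nb), function(j) {
    100 * profile_power_in(profile, band_edges[j], band_edges[j + 1]) / tot
  }, numeric(1))
  nm <- if (nb == 4) c("delta", "theta", "alpha", "beta") else paste0("band", seq_len(nb))
  tibble::tibble(band = nm, lo = band_edges[-(nb + 1)], hi = band_edges[-1], pct = pct)
}

#' Theoretical 95% spectral edge frequency
#'
#' Smallest frequency below which `quantile` of the profile's power within
#' `range` lies, from exact piecewise integration (inverted analytically per
#' segment).
#'
#' @inheritParams profile_density
#' @param quantile Power quantile, default 0.95.
#' @param range Hz range over which the edge is defined, default 0.5-40.
#' @return Frequency in Hz.
#' @export
theoretical_sef95 <- function(profile, quantile = 0.95, range = c(0.5, 40)) {
  tot <- profile_power_in(profile, range[1], range[2])
  assert_that(tot > 0, "profile has no power in the SEF range")
  target <- quantile * tot
  seg <- profile_segments(profile)
  seg <- seg[order(seg$lo), , drop = FALSE]
  acc <- 0
  for (k in seq_len(nrow(seg))) {
    a <- max(seg$lo[k], range[1]); b <- min(seg$hi[k], range[2])
    if (b <= a || seg$mass[k] <= 0) next
    dens_norm <- seg$mass[k] / powlaw_integral(seg$lo[k], seg$hi[k], seg$tilt[k])
    segpow <- dens_norm * powlaw_integral(a, b, seg$tilt[k])
    if (acc + segpow >= target - 1e-15) {
      need <- (target - acc) / dens_norm   # = integral of f^t over [a, f]
      t <- seg$tilt[k]
      f <- if (abs(t + 1) < 1e-12) {
        a * exp(need)
      } else {
        ((t + 1) * need + a^(t + 1))^(1 / (t + 1))
      }
      return(min(max(f, a), b))
    }
    acc <- acc + segpow
  }
  range[2]
}

#' Theoretical relative alpha variability
#'
#' Ratio (percent) of 6-14 Hz power to total 1-20 Hz power on the exact
#' profile spectrum — the band-ratio definition of RAV used for sedated ICU
#' recordings.
#'
#' @inheritParams profile_density
#' @param numerator,denominator Hz ranges of the ratio.
#' @return Percent.
#' @export
theoretical_rav <- function(profile, numerator = c(6, 14), denominator = c(1, 20)) {
  den <- profile_power_in(profile, denominator[1], denominator[2])
  assert_that(den > 0, "profile has no power in the RAV denominator range")
  100 * profile_power_in(profile, numerator[1], numerator[2]) / den
}

#' @export
print.spectral_profile <- function(x, ...) {
  cat("<spectral_profile>\n")
  nb <- length(x$band_fractions)
  bands <- paste(sprintf("%g-%g Hz: %.2f%%", x$band_edges[-(nb + 1)],
                         x$band_edges[-1], 100 * x$band_fractions),
                 collapse = ", ")
  cat("  bands:      ", bands, "\n", sep = "")
  cat(sprintf("  norm range:  %g-%g Hz\n", x$normalization_range[1], x$normalization_range[2]))
  cat(sprintf("  subdelta:    %.3f over %g-%g Hz, tilt %.3f\n",
              x$subdelta_mass, x$subdelta_band[1], x$subdelta_band[2], x$in_band_tilt))
  cat(sprintf("  amplitude:   %.2f uV RMS\n", x$amplitude_scale))
  invisible(x)
}

#' @method tidy spectral_profile
#' @export
tidy.spectral_profile <- function(x, ...) {
  theoretical_band_fractions(x)
}
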