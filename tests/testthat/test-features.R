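test_that("PSD peaks at the tone frequency and averages epochs correctly", {
  rec <- sine_recording(10, duration_s = 32)
  ep <- segment_epochs(rec, 8)
  psd <- power_spectrum(ep)
  expect_equal(psd$freqs[which.max(psd$power[1, ])], 10, tolerance = psd$resolution_hz)

  # two identical epochs average to the single-epoch PSD
  seg <- white_recording(duration_s = 8, n_channels = 1)
  two <- eeg_recording(cbind(seg$samples, seg$samples), fs = 256,
                       channel_labels = "c1")
  psd1 <- power_spectrum(segment_epochs(seg, 8))
  psd2 <- power_spectrum(segment_epochs(two, 8))
  expect_equal(psd2$power, psd1$power, tolerance = 1e-12)
  expect_equal(psd2$n_epochs_used, 2)
})

test_that("the PSD integral obeys Parseval within 5%", {
  rec <- white_recording(duration_s = 60, n_channels = 2, sd_uv = 3)
  psd <- power_spectrum(segment_epochs(rec, 8))
  for (ch in 1:2) {
    integral <- sum(diff(psd$freqs) *
                      (psd$power[ch, -1] + psd$power[ch, -length(psd$freqs)]) / 2)
    expect_equal(integral, stats::var(rec$samples[ch, ]), tolerance = 0.05 * 9)
  }
})

test_that("relative band powers: pure tone, flat spectrum, sum to 100", {
  rec <- sine_recording(10, duration_s = 32)
  psd <- power_spectrum(segment_epochs(rec, 8))
  bp <- relative_band_powers(psd)
  expect_gt(bp$pct[bp$band == "alpha"], 98)
  expect_lt(sum(bp$pct[bp$band != "alpha"]), 2)
  expect_equal(sum(bp$pct), 100, tolerance = 0.1)

  # analytic flat spectrum over 1-30 Hz with 1-4-8-13-30 bands
  grid <- seq(0.5, 40, by = 0.125)
  flat <- as_qeeg_psd(grid, as.numeric(grid >= 1 & grid <= 30))
  bf <- relative_band_powers(flat, band_edges = c(1, 4, 8, 13, 30),
                             normalization_range = c(1, 30))
  expect_equal(bf$pct, 100 * c(3, 4, 5, 17) / 29, tolerance = 0.5)
  expect_equal(sum(bf$pct), 100, tolerance = 1e-9)
})

test_that("spectral entropy has closed-form value for a two-bin spectrum", {
  grid <- seq(1, 40, by = 0.25)
  power <- numeric(length(grid))
  power[c(40, 80)] <- 3.7            # two equal nonzero bins
  psd <- as_qeeg_psd(grid, power)
  expect_equal(spectral_entropy(psd, range = c(1, 40)),
               100 * log(2) / log(length(grid)), tolerance = 1e-9)
})

test_that("spectral entropy separates tones from white noise and is scale-free", {
  tone <- power_spectrum(segment_epochs(sine_recording(10, duration_s = 32), 8))
  se_tone <- spectral_entropy(tone)
  noise <- power_spectrum(segment_epochs(white_recording(duration_s = 60), 8))
  se_noise <- spectral_entropy(noise)
  expect_lt(se_tone, 20)   # a Hann-tapered line occupies ~3 bins, not 1
  expect_gt(se_noise, 95)
  expect_gt(se_noise - se_tone, 60)
  # bounds and amplitude invariance
  expect_gte(se_tone, 0); expect_lte(se_noise, 100)
  scaled <- tone; scaled$power <- tone$power * 37.5
  expect_equal(spectral_entropy(scaled), se_tone, tolerance = 1e-12)
  # entropy is symmetric under permutation of bins within the analysis range
  grid <- seq(1, 39, by = 0.25)
  pw <- stats::runif(length(grid))
  base <- as_qeeg_psd(grid, pw)
  perm <- as_qeeg_psd(grid, sample(pw))
  expect_equal(spectral_entropy(perm, range = c(1, 39)),
               spectral_entropy(base, range = c(1, 39)), tolerance = 1e-12)
})

test_that("spectral edge frequency: tone, flat spectrum, quantile monotonicity", {
  tone <- power_spectrum(segment_epochs(sine_recording(10, duration_s = 32), 8))
  expect_equal(spectral_edge_frequency(tone), 10, tolerance = 0.3)

  grid <- seq(0.5, 40, by = 0.125)
  flat <- as_qeeg_psd(grid, rep(1, length(grid)))
  expect_equal(spectral_edge_frequency(flat), 0.5 + 0.95 * 39.5, tolerance = 1e-6)

  noisy <- as_qeeg_psd(grid, stats::runif(length(grid)))
  qs <- seq(0.2, 0.95, by = 0.15)
  sefs <- vapply(qs, function(q) spectral_edge_frequency(noisy, quantile = q),
                 numeric(1))
  expect_true(all(diff(sefs) >= 0))
})

test_that("RAV: all-in-band spectrum gives 100%, flat 1-20 gives 8/19", {
  grid <- seq(0.5, 40, by = 0.125)
  inband <- as_qeeg_psd(grid, as.numeric(grid >= 7 & grid <= 12))
  expect_equal(relative_alpha_variability(inband), 100, tolerance = 1e-9)
  flat <- as_qeeg_psd(grid, as.numeric(grid >= 1 & grid <= 20))
  expect_equal(relative_alpha_variability(flat), 100 * 8 / 19, tolerance = 0.5)
  short <- as_qeeg_psd(seq(2, 18, 0.5), rep(1, 33))
  expect_error(relative_alpha_variability(short), "cover")
})

test_that("aEEG limits: zero signal, sinusoid closed form, linear scaling", {
  zero <- eeg_recording(matrix(0, 1, 256 * 40), fs = 256, channel_labels = "c1")
  lim0 <- aeeg_limits(zero, feature_config(channels = "c1"))
  expect_equal(lim0$lower_uv, 0); expect_equal(lim0$upper_uv, 0)

  # stationary 10 Hz tone of amplitude A: envelope = 2 A gain(10)
  A <- 5
  rec <- sine_recording(10, amp_uv = A, duration_s = 60, n_channels = 1)
  lim <- aeeg_limits(rec, open_config(rec))
  expected <- 2 * A * (10 / 9)^0.6
  expect_equal(lim$upper_uv, expected, tolerance = 0.05 * expected)
  expect_equal(lim$lower_uv, lim$upper_uv, tolerance = 0.05 * expected)

  rec2 <- rec; rec2$samples <- rec$samples * 2.5
  lim2 <- aeeg_limits(rec2, open_config(rec))
  expect_equal(lim2$upper_uv, 2.5 * lim$upper_uv, tolerance = 1e-9)

  short <- sine_recording(10, duration_s = 10, n_channels = 1)
  expect_error(aeeg_limits(short, open_config(short)), "30 s")
})

test_that("extract_features is deterministic and validates channels", {
  prof <- make_band_profile(delirium_fractions())
  rec <- synthesize_recording(prof, duration_s = 40, fs = 256, seed = 5)
  f1 <- extract_features(rec)
  f2 <- extract_features(rec)
  expect_identical(as.data.frame(f1), as.data.frame(f2))
  expect_equal(nrow(f1), 9)  # 8 channels + mean
  expect_true(all(c("se", "aeeg_upper_uv", "sef95_hz", "delta_pct") %in% names(f1)))

  bad <- rec; bad$channel_labels[1] <- "XX"; rownames(bad$samples)[1] <- "XX"
  expect_error(extract_features(bad), "Fp1")
})

test_that("band fractions are amplitude-invariant while aEEG scales linearly", {
  prof <- make_band_profile(noncardiac_fractions(), amplitude_scale = 4)
  rec <- synthesize_recording(prof, duration_s = 40, fs = 256, seed = 9)
  big <- rec; big$samples <- rec$samples * 3
  f1 <- extract_features(rec); f2 <- extract_features(big)
  m1 <- f1[f1$channel == "mean", ]; m2 <- f2[f2$channel == "mean", ]
  expect_equal(m2$delta_pct, m1$delta_pct, tolerance = 1e-9)
  expect_equal(m2$se, m1$se, tolerance = 1e-9)
  expect_equal(m2$sef95_hz, m1$sef95_hz, tolerance = 1e-9)
  expect_equal(m2$aeeg_upper_uv, 3 * m1$aeeg_upper_uv, tolerance = 1e-9)
})

test_that("a delirium-profile recording is delta-dominated; white noise is flat", {
  rec <- synthesize_recording(make_band_profile(delirium_fractions()),
                              duration_s = 40, fs = 256, seed = 6)
  m <- extract_features(rec); m <- m[m$channel == "mean", ]
  expect_gt(m$delta_pct, m$alpha_pct)

  wn <- white_recording(duration_s = 60, n_channels = 8, sd_uv = 5)
  wn$channel_labels <- default_channels()
  rownames(wn$samples) <- default_channels()
  fw <- extract_features(wn); mw <- fw[fw$channel == "mean", ]
  expect_gt(mw$se, 95)
  # band fractions approach bandwidth ratios over the 0.5-30 normalization
  expect_equal(c(mw$delta_pct, mw$theta_pct, mw$alpha_pct, mw$beta_pct),
               100 * c(3.5, 4, 5, 17) / 29.5, tolerance = 1.5)
})
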