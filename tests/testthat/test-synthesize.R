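test_that("the same seed reproduces a recording bit for bit", {
  prof <- make_band_profile(delirium_fractions())
  r1 <- synthesize_recording(prof, duration_s = 8, fs = 256, seed = 7)
  r2 <- synthesize_recording(prof, duration_s = 8, fs = 256, seed = 7)
  expect_identical(r1$samples, r2$samples)
  r3 <- synthesize_recording(prof, duration_s = 8, fs = 256, seed = 8)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("realized RMS equals amplitude_scale and vanishes with it", {
  prof <- make_band_profile(noncardiac_fractions(), amplitude_scale = 7)
  rec <- synthesize_recording(prof, duration_s = 20, fs = 256, seed = 3)
  # disjoint-support components are exactly orthogonal: RMS is exact
  expect_equal(sqrt(mean(rec$samples[1, ]^2)), 7, tolerance = 1e-9)
  tiny <- prof; tiny$amplitude_scale <- 1e-6
  rec0 <- synthesize_recording(tiny, duration_s = 8, fs = 256, seed = 3)
  expect_lt(stats::var(rec0$samples[1, ]), 1e-10)
})

test_that("synthesis rejects invalid sampling setups", {
  prof <- make_band_profile(delirium_fractions())
  expect_error(synthesize_recording(prof, duration_s = 2), ">= 4")
  expect_error(synthesize_recording(prof, duration_s = 120, fs = 50), ">= 128")
})

test_that("empirical band powers match the profile via an independent periodogram", {
  prof <- make_band_profile(delirium_fractions())
  rec <- synthesize_recording(prof, duration_s = 120, fs = 256, seed = 21)
  # oracle: untapered periodogram from spec.pgram, integrated per band
  sp <- stats::spec.pgram(stats::ts(rec$samples[1, ], frequency = 256),
                          taper = 0, plot = FALSE, detrend = FALSE)
  band_power <- function(lo, hi) sum(sp$spec[sp$freq >= lo & sp$freq < hi])
  tot <- band_power(1, 30)
  emp <- c(band_power(1, 4), band_power(4, 8), band_power(8, 13),
           band_power(13, 30)) / tot
  expect_equal(100 * emp, 100 * delirium_fractions(), tolerance = 2)
})

test_that("power partitions across bands as specified (conservation property)", {
  for (fr in list(delirium_fractions(), noncardiac_fractions(), rep(0.25, 4))) {
    prof <- make_band_profile(fr)
    rec <- synthesize_recording(prof, duration_s = 30, fs = 256,
                                channel_labels = "c1", seed = 17)
    x <- rec$samples[1, ]
    n <- length(x)
    pw <- abs(stats::fft(x))^2 / n
    fg <- (0:(n - 1)) / n * 256
    tot <- sum(pw[fg >= 1 & fg < 30])
    for (j in 1:4) {
      edges <- c(1, 4, 8, 13, 30)
      frac <- sum(pw[fg >= edges[j] & fg < edges[j + 1]]) / tot
      expect_equal(frac, fr[j], tolerance = 0.02)
    }
  }
})

test_that("cohorts respect group sizes, labels and determinism", {
  groups <- tibble::tibble(
    label = c("cardiac", "non_cardiac"), n = c(5L, 4L),
    profile = list(make_band_profile(cardiac_fractions()),
                   make_band_profile(noncardiac_fractions()))
  )
  spec <- cohort_spec(groups, duration_s = 8, fs = 256, seed = 5L)
  coh <- synthesize_cohort(spec)
  expect_length(coh, 9)
  man <- cohort_manifest(coh)
  expect_equal(table(man$group_label)[["cardiac"]], 5)
  expect_equal(table(man$group_label)[["non_cardiac"]], 4)
  expect_equal(purrr::map_chr(coh, "group_label"), man$group_label)
  coh2 <- synthesize_cohort(spec)
  expect_identical(purrr::map(coh, "samples"), purrr::map(coh2, "samples"))
})

test_that("zero dispersion gives every subject the group-mean profile", {
  groups <- tibble::tibble(
    label = "g", n = 4L,
    profile = list(make_band_profile(delirium_fractions())),
    dispersion = list(profile_dispersion())
  )
  coh <- synthesize_cohort(cohort_spec(groups, duration_s = 8, seed = 2L))
  man <- cohort_manifest(coh)
  expect_length(unique(man$fractions), 1)
  expect_length(unique(man$amplitude_scale), 1)
})

test_that("logit-normal dispersion varies fractions but keeps them on the simplex", {
  groups <- tibble::tibble(
    label = "g", n = 6L,
    profile = list(make_band_profile(delirium_fractions())),
    dispersion = list(profile_dispersion(fractions = 0.3, amplitude = 0.1))
  )
  coh <- synthesize_cohort(cohort_spec(groups, duration_s = 8, seed = 2L))
  man <- cohort_manifest(coh)
  expect_gt(length(unique(man$fractions)), 1)
  fracs <- purrr::map(strsplit(man$fractions, ";"), as.numeric)
  for (f in fracs) {
    expect_true(all(f >= 0))
    expect_equal(sum(f), 1, tolerance = 1e-6)
  }
  expect_true(all(man$amplitude_scale > 0))
})

test_that("cohort-mean empirical delta power tracks the group mean fraction", {
  groups <- tibble::tibble(
    label = "g", n = 10L,
    profile = list(make_band_profile(delirium_fractions()))
  )
  coh <- synthesize_cohort(cohort_spec(groups, duration_s = 60, seed = 31L))
  deltas <- purrr::map_dbl(coh, function(rec) {
    x <- rec$samples[1, ]; n <- length(x)
    pw <- abs(stats::fft(x))^2
    fg <- (0:(n - 1)) / n * 256
    100 * sum(pw[fg >= 1 & fg < 4]) / sum(pw[fg >= 1 & fg < 30])
  })
  expect_equal(mean(deltas), 100 * delirium_fractions()[1], tolerance = 2)
})
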