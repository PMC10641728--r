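---
title: "Quantitative EEG biomarkers for ICU delirium cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EEG biomarkers for ICU delirium cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Postoperative delirium after cardiopulmonary-bypass cardiac surgery is
common, fluctuating, and frequently missed by bedside screening. A
candidate objective marker is the quantitative EEG (qEEG) profile of the
sedated patient during the first day in the ICU: published group
comparisons report slower spectra in cardiac-surgery patients — more
relative delta power, less alpha and beta, a lower 95% spectral edge —
and, within the cardiac arm, lower aEEG border amplitudes and an even
slower edge in the patients who became delirious.

`qeegicu` implements that analysis end to end as reusable, tested code:

1. a **synthetic EEG generator** whose *theoretical* spectral features can
   be set exactly to published group means, standing in for raw
   recordings that are not publicly deposited;
2. the **feature extractor** for the five standard qEEG parameter
   families: spectral entropy (SE), aEEG lower/upper border amplitudes,
   relative alpha variability (RAV), relative band powers, and the 95%
   spectral edge frequency (SEF95);
3. the **two-group statistical layer** used by such studies: Welch's
   *t*-test (from raw values or published mean ± SEM summaries), one-way
   ANOVA, exact and chi-square proportion comparisons, incidence
   percentages, and two-proportion sample sizes;
4. EDF input/output and a simulate → extract → compare **pipeline**.

## The spectral profile model

The generator describes a recording's power spectrum as a piecewise
model on 0.5–40 Hz:

* four clinical bands (default delta 1–4, theta 4–8, alpha 8–13, beta
  13–30 Hz) carrying **band fractions** that sum to one over a
  normalization range (default 1–30 Hz);
* an optional **sub-delta mass**: a proportion of total power lying below
  the normalization range (0.5–1 Hz), with density rising as $f^6$ toward
  the delta edge;
* a within-band **power-law tilt** $f^t$ applied inside every band without
  changing any band's total;
* an **RMS amplitude** in µV.

Because the model is piecewise power-law, every feature the extractor
computes has a closed form on the exact spectrum (`theoretical_sef95()`,
`theoretical_rav()`, `theoretical_band_fractions()`), which is what makes
calibration exact rather than approximate.

### Why a sub-delta term exists

Published tables of band fractions and SEF95 can be *mutually
inconsistent* if fractions are normalized over the band union alone. For
the delirium arm used throughout this package, cumulative printed power
at 8 Hz is 80.29 + 9.85 ≈ 90.1% — yet the printed SEF95 is 7.58 Hz,
which would require ≥ 95% of power below 7.58 Hz. The resolution adopted
here is power below the fraction-normalization range: slow-delta activity
that the spectral edge integrates over but that the printed
delta/theta/alpha/beta split excludes. `calibrate_profile(profile,
"sef95", target)` solves for exactly this mass by one-dimensional root
finding on the closed-form edge; a sedated, slow-wave-dominated EEG
plausibly carries half or more of its power there. Targets outside the
attainable range raise an error that names the range.

The sub-delta density shape ($f^6$ over 0.5–1 Hz) concentrates the mass
just below 1 Hz. This is deliberate: a mass hugging the 0.5 Hz analysis
edge would be partially smeared below 0.5 Hz by spectral-estimation
leakage and lost from the SEF integration range, biasing edge recovery.

### Calibration modes

* `sef95` → solves `subdelta_mass` (band fractions preserved exactly);
* `rav` → solves the within-band tilt (band fractions preserved exactly).
  Note the alpha band lies wholly inside the 6–14 Hz RAV numerator, so a
  profile can only reach RAV values near its own band-ratio; infeasible
  targets error with the attainable range.
* `aeeg_upper` → solves the RMS amplitude. The aEEG upper border is
  exactly proportional to amplitude, but has no closed form (it is a
  percentile of a smoothed envelope of filtered Gaussian noise), so the
  per-unit-amplitude value is measured once by a deterministic fixed-seed
  reference simulation through the package's own aEEG chain and the scale
  solved by linearity.

## Signal synthesis

Each channel is a sum of independent Gaussian noise components, one per
model segment, shaped in the frequency domain by the square root of the
segment density — an exactly zero-phase brick-wall filter, so components
occupy disjoint frequency supports and are exactly orthogonal. Each
component is rescaled so its realized power over the recording equals the
segment's share exactly; consequently band powers and total RMS are exact
by construction, and what the recovery tests measure is the *extractor's*
bias and variance, not generator luck. Channels are generated
independently (the features here are all channel-averaged, so spatial
covariance would not change any of them), and the same seed reproduces a
recording bit for bit.

Cohorts add between-subject variability on scales that respect the
parameter constraints: logit-normal jitter on band fractions
(renormalized to the simplex), log-normal on amplitude, logit-normal on
the sub-delta mass. `reference_group_dispersion()` maps published SEMs to
these scales by the delta method. Per-subject seeds derive from the
cohort seed by a stable integer hash, so a subject's data do not depend
on generation order.

What the generator deliberately does **not** emulate: artifacts other
than amplitude excursions, ECG/EMG contamination, sleep–wake cycling,
burst suppression, non-Gaussian waveform morphology, and inter-channel
correlation. Passing recovery tests therefore demonstrate that the
extractor is calibrated and unbiased under stationary Gaussian conditions
with known spectra — not that it is robust to every property of real ICU
EEG.

## Preprocessing and spectral estimation

* **Band-pass 0.5–40 Hz**, implemented as a zero-phase FFT
  (frequency-sampling) filter with raised-cosine transitions (0.25 Hz
  below the low edge, 4 Hz above the high edge). The passband is exactly
  flat and the filter idempotent; DC is removed exactly; 50/60 Hz mains
  lie beyond the upper stopband. A time-domain Butterworth applied
  forward–backward was rejected because its half-power point sits at the
  cutoff, which removes a visible share of 0.5–1 Hz slow-delta power and
  biases the spectral edge. The acquisition hardware band (0.1–40 Hz) is
  wider than the analysis band; the analysis filter governs the features
  and is the implemented default.
* **Epochs of 8 s with 50% overlap** (configurable). Each epoch is a
  single Hann-tapered window, giving 0.125 Hz resolution. The resolution
  choice is a bias trade-off, not cosmetic: the expected periodogram is
  the true spectrum convolved with the taper kernel, and at a band edge
  where density drops (e.g. delta→theta at 4 Hz) the kernel carries a net
  power flux into the quieter band proportional to kernel width. At
  0.25 Hz resolution (4 s epochs) this flux biases a delirium-grade delta
  fraction by about −2 percentage points; at 0.125 Hz it is about −1.
  The 50% overlap recovers the variance the taper discards. With 2-min
  recordings this yields 29 windows per channel.
* **Artifact masking**: epochs whose any-channel peak-to-peak exceeds
  200 µV are masked `"amplitude"`; epochs flat on all channels below
  0.1 µV are masked `"flatline"`. Masking never alters samples. The
  amplitude limit interacts with signal scale: a Gaussian channel at
  σ = 30 µV reaches ~200 µV peak-to-peak in an 8-s window by chance
  alone, which would censor the largest slow-wave epochs and bias spectra
  toward fast activity. The default generator amplitude (7 µV RMS) sits
  where published sedated-adult aEEG borders (12–16 µV) place it, far
  from the artifact limit.

## Feature definitions

All features are computed per channel on the epoch-averaged PSD and then
averaged over the eight 10/20 channels (Fp1, Fp2, C3, C4, T3, T4, O1,
O2), matching how such tables are reported. Referential channel labels
are used as given; the optional bipolar re-derivation was left out of
scope because every implemented feature is channel-averaged.

* **Relative band powers**: trapezoidal band integrals divided by the
  0.5–30 Hz integral, ×100. Band edges are conventional clinical values
  (0.5/4/8/13/30) and configurable.
* **SEF95**: smallest *f* with cumulative power over [0.5 Hz, *f*] at
  least 95% of the 0.5–40 Hz total, linearly interpolating the cumulative
  integral between grid points (removing grid-resolution bias).
* **Spectral entropy**: Shannon entropy of the range-normalized PSD over
  0.5–40 Hz, divided by log(#bins), ×100. This is the normalized-entropy
  convention; absolute agreement with proprietary anesthesia-monitor
  indices (which band-limit, window and rescale differently) is not a
  goal. Note the taper sets a floor for line spectra: a Hann-tapered pure
  tone occupies ~3 bins and scores ≈ 15–17, not ≈ 0.
* **RAV**: 100 × (6–14 Hz power)/(1–20 Hz power) on a 2-minute analysis
  window — the band-ratio definition used as a cerebral-blood-flow
  correlate in sedated recordings. A time-course variability statistic
  would be a different quantity and is intentionally not implemented.
* **aEEG borders**: band-pass 2–15 Hz with the classic rising response
  approximated by the fixed gain curve $(f/9)^{0.6}$ (≈12 dB/decade,
  unity at 9 Hz), peak-to-peak envelope over 0.5 s windows, 15 s
  moving-average smoothing, and the 10th/90th envelope percentiles as the
  lower/upper borders. Vendor aEEG implementations differ in unpublished
  details; every constant here is explicit in `feature_config()`. A
  stationary sinusoid of amplitude *A* maps to an envelope of
  $2A\,\mathrm{gain}(f)$, which the tests exploit as a closed form.

## Statistical layer

Welch's *t* (two-sided, Welch–Satterthwaite df) is computed identically
from raw samples or from published mean ± SEM summaries; with three or
more groups the comparison table switches to one-way ANOVA (whose F
equals the squared pooled *t* for two groups). Fisher's exact test
enumerates the full hypergeometric support and sums all tables with point
probability not exceeding the observed one (the standard "small-p"
two-sided rule; conventions differ, so it is documented). Both chi-square
variants (with and without Yates correction) are always reported, because
published incidence p-values often match neither exactly and the
generating test is usually unstated. No multiplicity adjustment is
applied by default, matching single-look exploratory qEEG tables; a Holm
option exists. Two-proportion sample sizes are provided under three
explicit conventions (unpooled normal, pooled normal, arcsine) — for a
35% vs 5% design at α = 0.05, power 0.80 they give 24, 27 and 12 per
group respectively, a spread worth being explicit about since published
power statements often cite a number none of the textbook formulas
reproduces exactly (e.g. 21).

## Numerical and design choices

* Zero-phase FFT filtering throughout (analysis band-pass, aEEG band);
  exactly flat passbands, no phase distortion of envelopes.
* Trapezoidal integration on the PSD grid; band edges aligned with the
  grid make the fraction partition exactly additive (fractions sum to
  100).
* Root finding with `uniroot` at tolerance 1e-12 on closed-form feature
  maps; calibrations verified to 1e-6 relative.
* Degenerate inputs are explicit errors: zero power in a feature range,
  all epochs rejected, groups of size one (SEM undefined), zero
  within-group variance in ANOVA, equal proportions in sample-size
  calculations.
* EDF output uses 1-s records, physical range = data range + 5% headroom,
  16-bit quantization (~range/65535 µV per step); the reader resamples
  mixed-rate files to the highest rate with a warning.

## Problem sizes used in the packaged checks

The recovery checks run at the study's own conditions: 120 s recordings,
256 Hz, 8 channels, group sizes 24/22 (surgery comparison) and 10/14
(delirium comparison). Unit and property tests use shorter recordings
(8–60 s) and smaller cohorts, which is ample for their closed-form
assertions. The Monte-Carlo pipeline check uses 60 s recordings over six
seeds: with between-subject dispersion matched to the published SEMs, the
delta-band Welch contrast at n = 10 vs 14 has true power ≈ 0.65, so the
check asserts a consistent direction of effect across seeds plus
significance in at least some — a claim the calibrated effect size
actually supports, unlike a near-certain-significance requirement.

## Known limitations

* The generator's stationary Gaussian model cannot probe robustness to
  real artifacts, nonstationarity, or montage effects.
* SE values depend on the taper and range conventions; only relative
  comparisons between groups processed identically are meaningful.
* The aEEG chain is a documented stand-in for unpublished vendor
  algorithms; absolute border values depend on its constants.
* Quantities requiring the original recordings (ventilation hours, ICU
  stay, the real-data ROC) are out of scope; the package reproduces the
  computational layer, not the clinical dataset.
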