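---
title: "Analyzing inferior colliculus responses to mouse vocalizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing inferior colliculus responses to mouse vocalizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icvocal)
```

## The problem

Mice communicate with a repertoire of social vocalizations that spans two
very different spectral regimes: ultrasonic vocalizations (USVs), whose
energy sits mostly above 45 kHz, and lower-frequency calls — the
low-frequency harmonic "squeak" (LFH), mid-frequency vocalizations (MFVs)
and broadband noisy calls — with substantial energy below 20 kHz. The
inferior colliculus (IC), the midbrain hub of the ascending auditory
pathway, is the first station where responses to these calls can be
related systematically to a neuron's frequency tuning. The analytical
question this package operationalizes is: *to what extent does a unit's
pure-tone frequency tuning predict whether it responds to a given call?*

`icvocal` implements the full analysis chain for multiunit spike data
recorded during playback of a 13-stimulus WAV set (10 vocal syllables,
broadband noise, 70 and 80 kHz tone bursts) and a tone-mapping protocol,
plus a synthetic-population generator that produces spike trains with the
same statistical structure so every stage can be exercised, calibrated and
stress-tested end to end without animal data.

## Stimulus model

Each playback stimulus is a `stimulus_descriptor`: duration, nominal peak
level, the −20 and −30 dB spectral band limits, the peak frequency, and a
set of `frequency_track`s — linear time–frequency segments at a given
amplitude relative to the stimulus peak. The packaged library
(`build_table1_library()`) encodes the tabulated acoustic features of the
10 syllables exactly; the *track geometry* behind those numbers is a
stylized invention (arches for chevron-type USVs, piecewise segments for
stepped USVs, fundamental-plus-harmonic stacks for the harmonic calls),
constrained so that synthesizing audio from the tracks and re-measuring
the −30 dB band limits with a Welch periodogram (Hann window, 1024-sample
segments at 500 kHz) recovers the tabulated limits to within one
1/3-octave step. Track amplitudes are sweep-rate compensated at synthesis
time because a linear chirp's power spectral density scales inversely
with its sweep rate.

The tone protocol (`build_default_protocol()`) uses a geometric grid
`4 * 2^(k/3)` kHz for k = 0..13 with a final tone capped at 90 kHz, so the
grid spans the full 4–90 kHz testing range with 15 points; levels run
10–80 dB SPL in 10 dB steps with 20 repetitions, plus a 0 dB catch level
that serves as the within-protocol estimate of background spiking for the
tuning analyses. The capped 15th point matters for the overlap analysis:
without it, no measured upper tuning limit could ever exceed 80.6 kHz,
and positive overlap with the highest-frequency syllable (lower limit
81 kHz) would be structurally impossible.

## Synthetic population

`sample_population()` draws ground-truth units from an explicit generative
model:

* **CF distribution** — a two-component mixture on log2 frequency: a
  dominant component with its mode at 14.5 kHz (SD 0.55 octaves) and a
  minor component at 51 kHz (SD 0.22 octaves), weighted 8% in females and
  18% in males. This reproduces a primary CF peak at 13–16 kHz, a
  secondary peak near 51 kHz that is larger in males, and keeps the mass
  at ≥ 40 kHz near 13%.
* **Tuning geometry** — a V-shaped threshold surface: threshold at CF
  (normal, mean 30 dB SPL, SD 8, clipped to 10–55) plus a linear
  dB-per-octave penalty with independently drawn slopes, 20–70 dB/oct on
  the low side and 15–60 dB/oct on the high side. The shallow high-side
  range is deliberate: it yields median upper tuning limits near
  30–40 kHz in the 20 kHz CF band with a wide spread, matching the
  reported heterogeneity of upper frequency limits, and it is what makes
  a sizable subpopulation genuinely responsive to stepped USVs.
* **Response model** — `drive()` gives the instantaneous rate increment:
  `gain × (effective level − threshold at the track's instantaneous
  frequency)`, maximized over active tracks and saturated at
  350 spikes/s. Effective level is playback level plus the track's
  relative amplitude. Broadband noise is treated as exciting the unit at
  the most favorable frequency inside its band. Polarity (70% excitatory,
  10% inhibitory-dominant, 20% unresponsive) signs the drive.
* **Spiking** — an inhomogeneous Poisson process by thinning against the
  1 ms-gridded rate `max(0, bg ± drive)`, with a 1 ms absolute refractory
  period. Background rates are Gamma(shape 3, mean 15 spikes/s): the
  recorded units are multiunit clusters, whose summed background sits
  well above single-unit rates. This choice also matters
  methodologically: below ~5 spikes/s the inhibition criterion
  degenerates, because chance all-trial silent stretches push the evoked
  upper CI to zero while the pooled background 5th percentile stays
  slightly positive, producing spurious "inhibitory" labels.

What the generator deliberately does *not* emulate: multipeaked or
combination-sensitive tuning, cochlear distortion products, adaptation
and offset responses, spike-sorting artifacts, and correlated noise
across trials. Passing recovery tests therefore shows that the analysis
chain is correct and well calibrated for threshold-governed,
rate-modulated Poisson units — not that real IC units satisfy those
assumptions.

## Spike density functions and responsiveness

`single_trial_sdf()` convolves each spike train with a Gaussian kernel and
samples it on a 1 ms grid; each spike carries unit mass, so the time
integral of the series equals the spike count up to edge loss (no
reflection is applied; a spike at the trial edge loses up to half its
mass, which is documented rather than corrected). The "10 ms width" of
the kernel is interpreted as an SD of 10 ms, the common convention for
spike density functions.

`bootstrap_sdf()` resamples trials with replacement (default 1,000
replicates) and reports the bootstrap mean and 95% percentile band.
`background_stats()` applies the same machinery to the no-sound trials
and summarizes the pooled distribution of bootstrap SDF values (over time
bins and replicates) by its mean and 5th/95th percentiles; the pooled
definition is one of several readings of "percentiles of the background
firing distribution" and was chosen because it is stable and directly
testable.

`classify_response()` marks a millisecond as significantly excited when
the lower CI of the evoked SDF exceeds the background 95th percentile,
and significantly suppressed when the upper CI falls below the 5th
percentile; the unit is responsive when either mask holds for at least
10 *consecutive* ms inside the analysis window. The window runs from
stimulus onset to 45 ms after offset by default (`window = "extended"`),
with the onset-to-offset window available as a configuration switch —
the two readings coexist in the method's description, and the extended
window is the one motivated by post-offset firing changes. Excitation
and suppression can co-occur (`"both"`); summaries count it as
responsive. On stimulus-free synthetic data this classifier's
false-positive rate is about 3–5% per unit–stimulus pair (documented
rather than asserted at 5%, since ~200 correlated 1 ms bins are screened
per window), essentially all of it from the inhibition arm.

A calibration simulation (`simulate_sdf_coverage()`) checks the pointwise
coverage of the 95% bootstrap CI on homogeneous Poisson trains
(20 trials at 20 spikes/s, 500 ms): coverage sits a little above 93%,
the expected mild undercoverage of a percentile bootstrap at n = 20.

## Frequency tuning

`build_fra()` tabulates mean spike counts in the 100 ms tone window per
frequency × level cell, keeping raw per-trial counts. `estimate_cf()` is
an automated surrogate for the by-eye selection of the FRA tip: a cell
"elicits firing" when its mean count exceeds the pooled 0 dB background
mean by 3 standard errors (of a 20-trial cell mean) and an absolute floor
of 0.5 spikes, and — because ~135 cells are screened per unit — a
qualifying cell must be supported by a qualifying neighbor (same
frequency one level up, or adjacent frequency at the same level), which
is how a human reader uses the contiguity of the response area. The
threshold criterion multiplier started at 2 SE, but at that setting
roughly one unit in ten acquired a spurious, spectrally distant CF from
chance-high cells; 3 SE with neighbor support recovers the true CF for
effectively all excitatory units at gain ≥ 2 (spikes/s)/dB while leaving
genuinely untuned units CF-less.

`bootstrap_bandwidth()` implements the tuning-bandwidth procedure: per
replicate, 20 spike counts are redrawn with replacement at each tested
frequency at the target level and a modified-Akima (makima) interpolant —
implemented in this package and verified against an independent
implementation — is fit through the resampled means on a 100-point grid.
Interpolation runs on log2 frequency, since the tone grid is geometric
and linear-frequency interpolation would distort the low-frequency side.
The 1,000 replicate curves give the bootstrap mean tuning curve and
percentile CIs. The background count is bootstrapped from the pooled
0 dB data with each replicate drawing 20 counts — the same sample size
as one tuning-curve frequency — so the two CIs being compared carry
matched sampling noise; resampling the full 300-count pool instead makes
the background CI several times tighter than the curve CIs and lets
chance-high frequencies qualify, inflating the upper limit. The
bandwidth limits are the lowest and highest interpolation-grid
frequencies whose lower curve CI exceeds the upper background CI, and
are undefined when no grid point qualifies.

## Overlap and categories

The overlap statistic is a plain signed difference in kHz:
`upper tuning limit − call's −30 dB lower spectral limit`, positive when
the unit's tuning reaches into the call's spectrum. The bootstrap point
estimate of the upper limit is used (not a CI bound), matching the
singular "upper limit" of the definition. `overlap_response_histogram()`
bins records at multiples of 10 kHz; `assign_category()` classifies the
10 syllables by spectral content (category 1: −30 dB lower limit at or
below 20 kHz; category 3: above 60 kHz; category 2: the stepped USVs in
between — a 5/2/3 split), and `category_summary()` produces the long
count table per group, exportable to any standard GLMM tool for a
Poisson mixed-model fit — the fit itself is out of scope here.

## Group statistics

`chi_square_cf()` compares two CF histograms as a 2 × k homogeneity
chi-square (a goodness-of-fit form is available when one distribution is
to be treated as reference), pooling adjacent bins from the
low-frequency end until every expected count reaches 5.
`kruskal_wallis()` wraps the standard tie-corrected rank test.
`benjamini_hochberg()` implements the step-up rule exactly as described —
rank the p-values, compare each to `(i/m) q`, reject up to the largest
rank that passes — and is cross-checked in the tests against brute-force
enumeration and `p.adjust`. A calibration simulation
(`simulate_bh_fdr()`) with 10 uniform nulls and 10 Beta(0.1, 1)
alternatives per replicate confirms the empirical FDR stays below
q = 0.05 (the theoretical bound under independence is `q·m0/m`, here
0.025).

## Problem sizes and reproducibility

The shared test fixture runs 120 synthetic units through the full chain
(tone mapping at nine levels plus WAV playback at 60 dB, 20 trials per
condition), which is large enough that the CF/bandwidth recovery rates
(targets ≥ 90% / ≥ 85%) and the overlap and category patterns are stable
across seeds while the whole suite stays inside a routine test run. The
calibration simulations use 10,000 replicates (FDR) and 500 replicates
(CI coverage), and `scripts/acceptance.R` recomputes both from scratch
with a caller-supplied seed. Every stochastic function takes an explicit
`seed` and restores the caller's RNG state; identical inputs and seed
give byte-identical outputs, including the simulated experiment tables.

## Known limitations

* The classifier's inhibition arm is intrinsically more permissive than
  its excitation arm at low firing rates; with 1 ms bins smoothed by a
  10 ms kernel, the 10 ms persistence requirement filters less than the
  bin count suggests.
* Band-limit measurement assumes the synthesized, noise-free stimuli;
  with recorded audio the −30 dB limits depend on the noise floor.
* The CF surrogate resolves ties toward lower frequencies and reports
  thresholds on the 10 dB level grid, so thresholds are upper bounds.
* Overlap uses a point estimate of the upper tuning limit; its bootstrap
  uncertainty is available but not propagated into the overlap records.
* The spike model is Poisson with a refractory floor; bursting,
  adaptation and offset responses are absent, so latency summaries on
  synthetic data are optimistic.
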