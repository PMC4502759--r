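---
title: "Methods: multitaper spectra, global coherence and bootstrap inference for infant anesthesia EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multitaper spectra, global coherence and bootstrap inference for infant anesthesia EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model of the data

`sevoeeg` re-implements, as a tested pipeline, the analysis chain used to
characterise age-dependent EEG dynamics in infants (0–6 months postnatal
age) under sevoflurane general anesthesia: surface-Laplacian re-referencing
of a 33-electrode modified 10/20 montage, anti-alias filtering and
downsampling to 256 Hz, multitaper spectrograms and group-median spectra,
frontal (F7–F8) coherograms, global coherence from the eigendecomposition of
a median-denoised cross-spectral matrix, frequency-domain bootstrap
confidence bands for group and paired spectral differences, and an
emergence analysis that bins EEG and behaviour by end-tidal sevoflurane
concentration (etSEVO).

No patient recordings are distributed with the original study, so the
package ships a first-class synthetic cohort generator whose templates
encode the study's qualitative structure: slow (0.1–1 Hz) and delta
(1–4 Hz) oscillations in all subjects; theta (4–8 Hz) and alpha (8–12 Hz)
oscillations only in the 4–6 month cohort during maintenance of a surgical
state of anesthesia (MOSSA); an overall broadband power offset between
cohorts; concentration-dependent decay of theta/alpha during emergence
below 1.2% etSEVO; and first gross body movement always below 1.2% etSEVO.

## The synthetic cohort generator

Each subject is a sum of narrowband stochastic oscillators plus independent
per-channel Gaussian noise. An oscillator is realised in the frequency
domain: independent complex Gaussian coefficients on the DFT bins inside
[center − bandwidth/2, center + bandwidth/2], zeros elsewhere, inverse FFT,
rescaled to the target rms. This randomized-phase construction has exactly
the configured band support, satisfies the energy bookkeeping identity
(total variance = Σ rms² when noise is off), and avoids the numerical
fragility of IIR band-pass filters at 0.1 Hz relative to a 1024 Hz rate.
Each oscillator has a single latent source multiplied by a fixed
per-electrode gain profile, plus independent channel noise; shared-source
gain therefore dials pairwise and global coherence continuously, which the
property tests exploit.

Two profile shapes are used. The broad profile (slow/delta) is
temporal-dominant with lower gains along the midline and vertex. This
matters because the surface Laplacian is a spatial high-pass: a spatially
uniform source is annihilated exactly, so profiles must carry genuine
gradients for oscillations to survive re-referencing — as real EEG sources
do. The theta/alpha profile is a Gaussian bump (σ = 0.8 rad) peaked at
F7/F8, giving the lateral frontal emphasis used by the recovery tests.

Default study conditions (the generator's defaults, not tuned afterwards):
11 subjects aged 0–3 months and 19 aged 4–6 months; native sampling rate
1024 Hz with one 256 Hz subject (the last), mirroring the one lower-rate
recording the cohort allows; timeline awake 40 s → induction 60 s →
MOSSA 660 s → emergence 600 s (MOSSA must be ≥ 600 s so a 10-min
constant-concentration window exists); etSEVO plateau 2.0% (younger) and
2.6% (older), the cohort medians; movement-onset concentration drawn from a
triangular distribution on [0.2, 1.0]% (younger) and [0.3, 0.6]% (older),
consistent with the reported medians and never reaching 1.2%. Absolute
microvolt amplitudes are configuration, not claims: they were chosen once
so that post-Laplacian band powers sit in the ranges the study reports
(slow ≈ +20 dB, delta ≈ +11 dB, theta ≈ +7 dB, alpha ≈ +6 dB in the older
cohort; theta/alpha below 0 dB in the younger cohort), with a −6 dB
broadband offset for the younger cohort.

What the generator does *not* emulate: volume conduction from a biophysical
head model, non-Gaussian artifacts (movement, electrocautery), electrode
impedance drift, and state transitions with hysteresis. Tests passing on
synthetic cohorts therefore validate the *pipeline arithmetic* —
estimators, denoising, inference, binning — not clinical generalisation.

## Preprocessing

*Montage geometry.* Electrode positions are the idealized unit-sphere 10/20
construction (vertex at inclination 0, circumference ring at 72°, interior
rows by arc interpolation). "Distance along the scalp" is the great-circle
distance; no individual head geometry was published. Neighbor sets are the
Delaunay edges of the azimuthal-equidistant projection with edges longer
than 1.6× the median great-circle edge removed — a reproducible definition
of "nearest neighbor" sets. Laplacian weights are inverse-distance,
normalized to sum to one per electrode; inverse distance is our documented
kernel choice (the weighting kernel is not otherwise specified). Ear
electrodes M1/M2 are excluded from all analysis.

*Filtering.* The anti-alias filter is a zero-phase symmetric FIR
(Blackman-window design, −6 dB at 80 Hz, stop-band attenuation beyond
60 dB well before the output Nyquist of 128 Hz; 129 taps at 1024 Hz,
65 at 256 Hz), applied with reflect padding so constants are preserved
exactly, followed by integer decimation to 256 Hz.

*Epoch rules.* MOSSA: one 300-s epoch centered in the first 600-s window
whose etSEVO stays within ±0.1% of the window median (and whose median
exceeds 0.2%, i.e. gas actually on). Awake: one 11-s epoch before the
concentration first rises. Movement comparison: a 20-s MOSSA epoch starting
600 s before gas-off (gas-off = one second past the last increase of the
trace) paired with a post-movement epoch of 5–30 s starting at the first
gross body movement. Emergence: at most one artifact-free epoch per 0.3%
etSEVO bin ([0, 0.3) … [2.7, 3.0)), 30 s preferred with 20 s and 15 s
fallbacks, every sample inside the bin. Visual artifact screening is
replaced by an automated amplitude rule: samples exceeding 200 µV (default,
configurable) on any channel are flagged, and epochs with more than 10%
flagged samples are rejected. Epochs are half-open `[t_start, t_start +
duration)` in seconds from recording start, and all carry subject, state
and time provenance.

## Multitaper estimation

Spectrograms use T = 2 s windows with 1.9 s overlap, time-bandwidth product
TW = 2 and K = 3 DPSS tapers (half-bandwidth W = TW/T = 1 Hz). Tapers are
computed from the classical symmetric-tridiagonal eigenproblem, orthonormal
and ordered by spectral concentration; concentration is verified in tests
against an independent sinc-kernel quadratic form. The FFT length equals
the window length (512 samples at 256 Hz; no zero padding), giving a 0.5-Hz
grid — zero-padding behaviour in the original toolchain is unstated, and
the no-padding grid is our documented choice. Windows are demeaned before
tapering (drift control). Power is one-sided density in µV²/Hz; dB means
10·log10. The slow band's 0.1-Hz lower edge is below the grid resolution;
on the 0.5-Hz grid the slow band comprises the 0.5 and 1.0 Hz bins (never
DC) — a documented limitation. Other bands take bins with lo < f ≤ hi.

Group summaries: the group-median spectrogram is the element-wise median
across subjects *in dB* (the scale on which the group maps are drawn;
whether medians were taken in dB or linear power is unstated, and dB is our
documented convention). The group spectrum takes each subject's time-mean
in linear power first (energy average), converts to dB, then takes
cross-subject median and 25th/75th percentiles with linear-interpolation
(type 7) quantiles. Band topography averages the time-mean of the
group-median spectrogram over each band's bins, per electrode.

## Coherence and global coherence

Coherence uses T = 2 s non-overlapping windows with TW = 3, K = 5. The
pairwise coherogram is |S_ij|/√(S_i S_j) per window with cross- and
auto-spectra averaged over tapers; values are clamped at 1 against rounding
excess and undefined bins (zero auto-spectrum) are NA.

The cross-spectral matrix is estimated per non-overlapping window, then
denoised by taking element-wise medians of the real and imaginary parts
over consecutive blocks of 10 windows. A 5-min epoch yields 15 blocks; the
original description covers a single median step, so averaging independent
block medians is our documented extension for long epochs. Global coherence
is λ_max/Σλ from the Hermitian eigendecomposition per frequency; the
principal mode's squared magnitudes give the per-electrode spatial
coherence map, band-averaged.

A numerical point worth flagging: element-wise medians do **not** preserve
positive semi-definiteness. On realistic data the denoised matrix carries
small negative eigenvalues (≲ 1% of the trace). `global_coherence()`
therefore clamps negative eigenvalues to zero up to a relative tolerance
(`psd_tol = 0.05` of the trace) and rejects anything more indefinite. With
exactly rank-one input the ratio is still 1 to within 1e-8, as the
acceptance checks require.

## Frequency-domain bootstrap

For each subject the spectrum entering inference is the time-mean
multitaper spectrum with degrees of freedom m = K × n_windows (m is not
otherwise specified; tying it to the estimator's degrees of freedom
preserves the replicate's sampling variance). A replicate draws, per
frequency, m complex Fourier coefficients with real and imaginary parts
Normal(0, S(f)/2) and averages their squared magnitudes; the package draws
directly from the exactly equivalent Gamma(shape = m, scale = S(f)/m) law,
which is also the closed-form oracle the tests verify against
(Kolmogorov–Smirnov at m = 30). Per bootstrap replicate, cross-subject
medians are taken per group in dB (paired variant: median of within-subject
dB differences) and differenced per frequency; the 95% band is the
percentile envelope over 2000 replicates (500 in scaled-down property
runs), and a frequency is "significant" when its band excludes zero. No
multiple-comparison correction is applied, mirroring per-frequency CI
bands; `band_significance()` adds a band-level fraction for testability.

A caveat the package documents rather than hides: under a pure null
(both groups drawn from one spectrum, all variance being measurement
noise), the percentile interval of a *median* statistic built from
re-noised subject spectra is conservative — empirical coverage is ≈ 98–99%
rather than 95%. A control simulation with the mean statistic under the
identical protocol gives ≈ 93–95%, isolating the effect to the interaction
of the median with parametric re-noising. The procedure is implemented as
specified; its conservatism simply means its significance calls are, if
anything, cautious.

## Emergence and behaviour

Band power per etSEVO bin is each subject's band-mean of the time-mean
spectrum of its binned epoch, summarised by group medians (medians chosen
for consistency with every other group summary). The movement table counts
a subject as moving in the bin containing its first-movement concentration,
with denominators equal to the subjects contributing EEG data to that bin
(denominators are not otherwise specified; this is our documented choice).

## Pipeline, determinism and problem sizes

`run_pipeline()` executes generate → preprocess → spectral → coherence →
bootstrap → emergence, streaming one subject at a time (a raw default
recording is ~370 MB, so recordings are generated, preprocessed, epoched
and discarded). One master seed fans out deterministically: subject i uses
seed (master + 104729·i) mod (2³¹ − 1); within a subject the EEG, the
etSEVO jitter and the movement draw use seed, seed + 1, seed + 2; the
bootstrap uses the derived index 999. Two runs with one configuration are
bit-identical, verified on output-file MD5 hashes in the manifest. The
YAML-config CLI (`inst/cli/sevoeeg.R`) is a thin wrapper over the exported
functions.

Problem sizes used by the test suite are the package's own choices: unit
tests run subjects at 256 Hz native rate with the shortest admissible
timeline; property tests use 3–8 subjects or fabricated spectra; the
determinism and recovery checks run the full 30-subject default cohort; the
null-coverage check uses 200 outer replications at 500 inner replicates.

## Known limitations

* The spatial model is a gain profile, not a forward model; spatial maps
  validate bookkeeping, not physiology.
* The slow band is represented by two grid bins; sub-0.5 Hz structure is
  not resolved.
* The amplitude-threshold artifact rule is a stand-in for expert visual
  screening and will not catch low-amplitude artifacts.
* The bootstrap's conservatism under pure measurement-noise nulls is
  inherent to the median/percentile construction (above).
* EDF output quantizes to 16 bits of each channel's observed range.
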