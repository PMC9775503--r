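---
title: "Measuring neural entrainment to musical pulse: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring neural entrainment to musical pulse: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

When people listen to music, slow cortical activity phase-locks to the
music's rhythmic structure: the pulse (the beat one taps to, typically
0.5-4 Hz with a mode near 2 Hz), groupings of beats (subharmonics), and
subdivisions of the beat (harmonics, 4-8 Hz). Measuring this entrainment for
*self-selected*, naturalistic music is awkward because every recording has
its own pulse frequency and may drift in tempo. `pulselock` implements a
complete pipeline for this measurement problem:

1. detect each recording's pulse, subharmonic and harmonic frequencies with
   a gradient-frequency network of nonlinear oscillators;
2. restrict analysis to a stable-tempo epoch of at least two minutes;
3. quantify entrainment as the wavelet phase-locking value (PLV) between the
   music's amplitude envelope and each EEG channel;
4. re-express every PLV spectrum on a dimensionless metrical axis on which
   the pulse sits at 2, so recordings with different tempi can be averaged;
5. aggregate across recordings, electrodes and participants and test level,
   group and electrode-cluster contrasts with linear mixed models.

Because no public recording/EEG corpus accompanies this design, the package
also contains a first-class synthetic-data generator that produces music and
EEG with *known* pulse structure and coupling strength, which is what the
test-suite and the acceptance script exercise.

## Audio front end

The audio chain mimics early auditory transduction followed by onset
extraction. A 4th-order Butterworth band-pass (0.5-5 kHz; upper edge capped
at 90% of Nyquist when the sample rate requires it) stands in for the
middle-ear transfer function. Onsets are detected in the complex STFT
domain (46-ms Hann window, 11.6-ms hop, about 86 frames/s): each frame is
compared against a prediction that carries the previous frame's magnitude
and a linearly extrapolated phase, and the summed complex deviation
`sum_k |X_k(n) - Xhat_k(n)|` forms the onset-strength signal. Steady-state
content is predicted exactly and vanishes; attacks are not. The curve is
median-detrended (1-s running median) and half-wave rectified.

The amplitude envelope — the stimulus-side signal of the PLV — is the
magnitude of the analytic signal of the middle-ear-filtered waveform,
low-passed at 50 Hz and resampled to the 1000-Hz EEG analysis rate. The
estimator sits behind an `envelope.method` knob because several broadly
equivalent definitions circulate in the literature.

## Pulse and meter from a gradient-frequency oscillator network

A bank of 76 canonical Hopf oscillators, log-spaced at 15 bins per octave
over 0.25-8 Hz (matching the wavelet grid below), is driven by the common
onset signal `s(t)`:

    dz_i/dt = f_i * [ z_i (alpha + i 2 pi + beta1 |z_i|^2
              + eps beta2 |z_i|^4 / (1 - eps |z_i|^2)) + c s(t) ]

with the critical regime `alpha = 0`, `beta1 = -1`, `beta2 = -0.25`,
`eps = 1`, `c = 1`: undriven oscillators decay, driven ones grow selectively
near the forcing frequencies and their harmonic ratios. Integration is
fixed-step RK4 at 250 Hz after resampling the onset signal; the damping
denominator is floored during RK4 stages so a forcing spike transiently
crossing `|z|^2 = 1/eps` damps hard rather than diverging numerically (a
genuine blow-up of the accepted state still raises an error naming the
oscillator and time).

Two forcing-preparation choices matter and are deliberate:

* **Onset smoothing (0.25-s raised cosine).** A percussive click train has a
  nearly flat harmonic comb, and critical-Hopf amplitudes compress roughly
  with the cube root of forcing, so without any spectral rolloff the second
  or third harmonic of a slow pulse (0.8-1.25 Hz) can out-compete the
  fundamental inside the delta range. Broadening each onset pulse makes the
  forcing spectrum fall off with harmonic number — the same role perceptual
  accent and attack width play in real music. The width was fixed once
  against the five-frequency fixture grid (0.8-3.2 Hz) during development.
* **Amplitude normalization.** The smoothed onset signal is scaled so its
  99th percentile is 1, making the coupling gain comparable across
  recordings; salience rankings are invariant to rescaling the input.

Salience is the time-averaged amplitude per oscillator. The pulse is the
most salient frequency at or below 3.5 Hz; the harmonic is the most salient
oscillator at or above 3.5 Hz lying within 6% of an integer multiple of the
pulse; the subharmonic the most salient oscillator near pulse/2 or pulse/3.
Ties break toward the lower frequency (the slower, more commonly perceived
pulse). A delta-range profile whose peak is not a local maximum, or whose
peak-to-median ratio falls below 2, yields a "no pulse detected" failure —
this gate rejects white-noise forcing (ratio about 1.4 on noise, 3.4-10 on
clean fixtures) while passing every clean fixture.

**Stable epochs.** A 10-s window slides at 1-s hops; the three tracked
frequencies must each stay within 4% ("a few percent") of their interval
median over at least 120 s, tracks absent in more than half the windows
being ignored. Because a 10-s window overlapping a tempo jump can already
vote for the new tempo, a fine-grained check additionally requires every
1-s delta-range amplitude argmax inside the epoch to stay within one grid
bin of the epoch pulse; the first 3 s of the run are exempt (the bank rings
up from rest, which is not a property of the stimulus). On a fixture
stepping from 2 to 2.6 Hz at 60 s this places the epoch start at 61 s.

## Wavelet PLV

Both the envelope and each preprocessed EEG channel are convolved with 65
complex Morlet wavelets, `f_k = 0.25 * 2^(k/15)` Hz for k = 0..64 (0.25-5
Hz, 15 bins per octave). The cycle count doubles the center frequency and
rounds, clamped to 3-8 cycles; the clamp reconciles the doubling rule
(which alone would give 1-10 cycles over this range) with the intended 3-8
range. Note that `round(2f)` makes the spectral bandwidth
`sigma_f = f / cycles` approximately 0.5 Hz wherever the clamp is inactive,
so chance levels are comparable across the mid-range wavelets.

For channel j and wavelet k the phase-locking value is

    PLV_jk = | n^-1 sum_t exp(i (theta1_kt - theta2_jkt)) |,

the magnitude of the mean resultant relative-phase vector, in [0, 1].
Samples within one wavelet half-support (4 sigma) of either signal edge are
excluded and `n` counts only the samples actually used; coefficients of
numerically zero magnitude (degenerate input) are flagged invalid rather
than contributing arbitrary phases. The production path normalizes the
complex coefficients directly instead of materializing phase matrices; the
test-suite verifies it against a literal direct summation to 1e-12.

For i.i.d. uniform relative phases the expected PLV is `sqrt(pi)/(2 sqrt(n))`
(about 0.0089 at n = 10,000) — the chance floor every level comparison sits
on.

**Pulse normalization.** The frequency axis is rescaled by
`u(f) = 2 f / pulse`, and each channel's PLV-vs-log2(f) curve is linearly
interpolated onto a fixed dimensionless grid (15 bins per octave over
0.5-8). Interpolation is used rather than an integer bin shift because
`15 log2(2/pulse)` is generally fractional (pulse 2.5 Hz: 4.83 bins). Grid
points outside the measured 0.25-5 Hz range are missing, never
extrapolated; consequently the off-harmonic level u = 5 is unmeasurable for
recordings with pulse above about 1.9 Hz, and level extraction reports it
as missing. Scalar level values at u in {1, 1.5, 2, 3, 4, 5} (subharmonic,
off-subharmonic, pulse, off-pulse, harmonic, off-harmonic) are read off the
normalized curve by interpolation in log2(u).

## EEG preprocessing

The deterministic chain: trim to 1 s around the stimulation events;
anti-aliased down-sampling to 1000 Hz; re-referencing to the bilateral
mastoids TP9/TP10 (reference rows dropped); zero-phase Hamming windowed-sinc
FIR band-pass 1-55 Hz (transition width 25% of cutoff); a zero-phase biquad
notch (Q = 30) at the line frequency; and joint-probability bad-channel
flagging at 5 s.d. The bad-channel score is the mean negative log
probability of each channel's samples under a pooled-ensemble histogram
density, normalized leave-one-out — a single aberrant channel would
otherwise inflate the ensemble s.d. enough to mask itself. Artifact
subspace reconstruction, ICA-based artifact removal and spherical channel
interpolation are intentionally out of scope: they target biological
artifacts that synthetic data does not contain, and externally preprocessed
real data can enter the pipeline at this stage's output contract.

## Group-level statistics

Per participant, level values are averaged over all recording-by-channel
cells (grand average), and per cluster over the cluster's six electrodes
(nine canonical auditory-research clusters). Group confidence intervals are
bias-adjusted normal-approximation bootstrap intervals over participants
(10,000 resamples). Pulse-frequency distributions are compared between
groups with the two-sample Kolmogorov-Smirnov test.

Contrasts are fit with linear mixed models (lme4/lmerTest), type-III F
tests and Satterthwaite degrees of freedom: `plv ~ level * group +
(1 | participant)` for grand averages and `plv ~ cluster * group * level`
with uncorrelated random intercept/slope terms
`(1|participant) + (1|participant:cluster) + (1|participant:level)` for the
topographic model, fitted on participant-by-cluster-by-level cell means.
Holm's step-down correction controls the family-wise error across the
F tests of a model. When a mixed fit fails, a documented paired-contrast
approximation takes over (per-participant level differences; Welch tests
across groups).

## The synthetic-data generator

`gen_music()` renders percussive events as 5-ms raised-cosine noise bursts
(20 ms for the `burst` timbre) at onset times dictated by a
piecewise-constant tempo profile, with every `meter`-th event accented
(unaccented events at 60% amplitude) and an optional broadband noise floor.
The returned ground truth (onset times, accent flags, pulse track) is exact
by construction. `gen_eeg()` synthesizes each channel as
`sum_level kappa * cos(envelope phase at the level frequency + jitter)`
plus 1/f noise; the phase jitter is an Ornstein-Uhlenbeck process with 1-s
correlation time so that it is slow relative to the wavelet analysis and
genuinely degrades locking (white phase jitter would simply average out).
Downstream PLV is monotone in kappa, verified over a kappa grid.

Cohorts mirror the study design: two groups (YA/OA) of `n_per_group`
participants with six recordings each, per-recording pulse frequencies
drawn from a log-normal distribution with mode 2 Hz truncated to 0.5-4 Hz,
a multiplicative OA/YA coupling ratio, and optional
(group, cluster, level) coupling modifiers. Default coupling
(`kappa` 0.3 at pulse, 0.15 at subharmonic/harmonic, unit 1/f noise, 1-rad
jitter) was chosen once to produce pulse-level PLVs around 0.2-0.4 —
moderate, realistic locking — and is not adjusted per experiment. Note the
generator's pulse range extends to 4 Hz while the detector's delta boundary
is 3.5 Hz, so a small fraction of drawn recordings is genuinely
undetectable and excluded — attrition analogous to real cohorts.

What the generator does *not* emulate: melody and harmony, genre-specific
spectral balance, expressive micro-timing, biological EEG artifacts
(blinks, muscle, drift) and volume conduction. Passing tests therefore
demonstrate that the pipeline recovers known rhythmic and coupling
structure through the full signal path — not that it is robust to every
property of real recordings.

## Simulation scales and numerical choices

Full-resolution runs (12-kHz audio, 1000-Hz EEG, 65 wavelets, 56 channels)
are exercised on single recordings and miniature cohorts. Group-level
simulation studies (parameter recovery across 20 replicate cohorts of
8 + 8 participants, and a 200-replicate type-I study) run the same PLV,
normalization and model code at reduced scale: 32-Hz sample rate, 30-s
recordings, and only the wavelets bracketing the levels under test — sizes
chosen so the studies complete in minutes while the per-recording sample
count (about 960) keeps the chance floor near 0.03, far below the coupled
PLVs. The pulse is fixed at 2 Hz in these studies so wavelet subsets can be
shared across recordings; the normalization step still runs per recording.

One property discovered during development deserves emphasis: with *no*
coupling anywhere, the chance PLV at the pulse level exceeds that at the
off-pulse level, because the envelope's deterministic pulse component and
the narrowband-filtered noise rotate at the same frequency, so their
relative phase drifts slowly instead of spinning. A "global null" for the
level contrast must therefore make the levels exchangeable — the type-I
study places equal-amplitude stimulus components at both tested levels
(`env_amps = c("2" = 1, "3" = 1)`) with kappa = 0. This is a property of
the phase-locking statistic at finite epoch length, not an inference
defect; it also implies that empirical pulse-vs-off-pulse contrasts carry a
small structural bias favoring the pulse whenever epochs are short.

Other numerical choices: wavelet kernels are truncated at 4 sigma and
normalized to unit gain at their center frequency; convolutions run via FFT
with kernels centered at lag zero so outputs align without per-kernel
trimming; seeds derive from a single user seed through a fixed linear
recurrence, keeping every artifact bit-reproducible; equal oscillator
saliences break toward the lower frequency; the delta/theta boundary
3.5 Hz is inclusive on both sides, with the pulse taking precedence at
exactly 3.5 Hz.

## Known limitations

* The middle-ear filter and envelope estimator are reasonable stand-ins
  implemented behind named configuration options; no claim is made that
  they reproduce any specific published transfer function.
* The oscillator bank is single-layer and non-adaptive; real tempo
  *fluctuation* (as opposed to step changes) within the stability tolerance
  is averaged, not tracked.
* Pulse frequencies above 3.5 Hz are undetectable by the delta-range rule.
* The off-harmonic level (u = 5) is missing for pulse frequencies above
  about 1.9 Hz, and off-level values adjacent to strong levels absorb a few
  percent of spectral leakage through interpolation at 15 bins/octave.
* Mixed-model cluster analyses are fit on cell means rather than
  recording-level data; denominator degrees of freedom are accordingly
  smaller than a recording-level fit would give.
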