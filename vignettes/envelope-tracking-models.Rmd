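---
title: "Evoked responses versus oscillatory entrainment in speech envelope tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evoked responses versus oscillatory entrainment in speech envelope tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgetrack)
```

## The scientific question

Low-frequency (1–10 Hz) neural activity recorded over auditory cortex
phase-aligns to the amplitude envelope of speech.  Two mechanisms can
produce this "envelope tracking":

* **Oscillatory entrainment** — an endogenous neural oscillator is
  phase-corrected by discrete acoustic landmarks and keeps reverberating
  between them;
* **Evoked responses** — every landmark triggers a stereotyped transient
  response, and the superposition of these transients mimics phase
  alignment without any oscillator.

The landmark driving both candidate processes is the *acoustic edge*
(**peakRate**): a local maximum in the first temporal derivative of the
amplitude envelope, marking a rapid amplitude rise near vowel onset.
`edgetrack` implements generative models of both mechanisms, the phase
statistics that discriminate them, and a synthetic-data module that
emulates the event statistics of natural and 3×-slowed speech, so that
the full analysis pipeline is testable end-to-end without audio corpora
or neural recordings.

The key experimental idea is that at the *regular* speech rate
(≈5.7 edges/s) the two models make almost identical predictions, because
the duration of one evoked response (≈350 ms) spans about two cycles at
the speech rate.  Slowing speech to one-third rate (≈1.9 edges/s) pulls
these scales apart and produces two discriminating predictions:

1. **Spectral**: the inter-event phase coherence (IEPC) profile of the
   evoked-response model shows *two* peaks — one in the theta range
   reflecting the shape of the evoked response, one at the event rate
   (≈1.9 Hz) reflecting its frequency of occurrence — whereas the
   oscillator model shows a *single* peak at its natural frequency.
2. **Temporal**: after an isolated edge, the oscillator's phase coherence
   stays elevated for multiple cycles (reverberation), whereas the
   evoked-response model returns to chance within one cycle.

`run_full_comparison()` reproduces both predictions on synthetic data.

## The two generative models

Both models receive the same input: a series $s(t)$ containing the
peakRate magnitudes — min–max scaled within each rate condition to
$[0.5, 1]$, reflecting rate-normalized edge encoding — as single-sample
impulses at event times, and zeros otherwise
(`build_event_input()`).  Gaussian temporal jitter (SD 10 ms regular /
30 ms slow) is applied to impulse placement only; all phase analyses use
the original unjittered times.

**Oscillator model** (`simulate_oscillator()`): a coupled phase–amplitude
system

$$\frac{d\theta}{dt} = 2\pi F - c\,s(t)\,r\sin\theta, \qquad
  \frac{dr}{dt} = r(1 - r^2) + c\,s(t)\cos\theta,$$

with a limit-cycle attractor at $r = 1$, natural frequency $F$ matched to
the speech rate (5.7 / 1.9 Hz), and phase correction toward $\theta = 0$
at events.  The predicted response is $\cos\theta \cdot r$.  Integration
is forward Euler at 400 Hz: the system is slow relative to the step, the
free-run phase increment $2\pi F/f_s$ is then exact, and the coupling
calibration has the closed form $c = \phi\,\pi f_s$, where $\phi$ is the
fraction of the maximal phase shift (taken as $\pi$, the largest
meaningful correction distance) produced by a unit event at
$\theta = \pm\pi/2$.  The working value is $\phi = 0.7$: strong enough
for a rate-matched oscillator to entrain, weak enough that mismatched
oscillators do not (`scan_coupling()` reproduces this selectivity).
Events are single-sample impulses, so the effective per-event kick is
$c\,s\,r\sin\theta/f_s$; the calibration folds $f_s$ in.

Two numerical notes on the driven system.  First, impulsive kicks can
push $r$ through zero; because $(-r, \theta)$ and $(r, \theta + \pi)$
describe the same state — both equations and the prediction are invariant
under the flip — the simulator normalizes to $r \ge 0$ at every step,
which changes nothing dynamically but keeps the amplitude interpretable.
Second, the entrainment score of `scan_coupling()` is the concentration of
the *band-limited predicted-response phase* at event times rather than of
the raw state angle, which the $\pi$ jumps of amplitude flips would
scatter even under clean locking.  At couplings well above the calibrated
value this implementation does not show entrainment spreading across
oscillator frequencies; the amplitude dynamics destabilize and coherence
collapses for every frequency instead.  The regimes the scan exists to
establish — chance-level coherence without coupling, and entrainment
confined to the rate-matched oscillator at the calibrated intermediate
coupling — are robust.

**Evoked-response model** (`convolve_kernel()`): linear convolution of
$s(t)$ with an evoked-response kernel defined on lags −150…450 ms.  In
applications the kernel is estimated from recordings with a time-lagged
linear encoding model (`estimate_trf()`, ridge regression on the lagged
design, with the penalty chosen by held-out generalization error when not
given); for synthetic work `generate_synthetic_kernel()` provides a
biphasic-plus-rebound waveform with ≈350 ms support, spectrally peaked
near 4 Hz with genuine delta-band content — the shape of a typical
auditory evoked field, not an idealized zero-mean wavelet.  That delta
content matters: a spectrally too-clean kernel suppresses exactly the
low-frequency coherence that distinguishes the evoked model's two-peak
signature.

**Noise model** (`add_pink_noise()`): Gaussian noise shaped to a $1/f$
magnitude spectrum (linear-phase FIR fit to the target; relative
magnitude error below 1% across the analysis range, which matters because
percent-level ripple in the noise spectrum visibly imprints itself on
IEPC spectral profiles).  The stated signal-to-noise ratio of 1/10 is
interpreted as a *power* ratio — the usual dB convention — giving an
amplitude-RMS ratio of $1/\sqrt{10} \approx 0.316$, which is the
`noise_config()` default.  Under a literal amplitude reading (0.1) the
delta-band signal is ≈4× below the noise floor in every band and the
evoked model's low-frequency IEPC peak cannot be resolved at any
realistic ensemble size; under the power reading the two-peak prediction
is robustly reproduced.  The parameter remains configurable.

To keep results independent of particular noise draws, analyses are
averaged over a randomization ensemble (`run_randomized_ensemble()`):
64 temporal-jitter realizations × 40 amplitude-noise realizations = 2560
per model and condition by default; a reduced 8 × 5 profile
(`edge_track_config(fast = TRUE)`) is used for routine runs and testing.

## The synthetic stimulus: a quasi-periodic syllabic pacemaker

The event generator (`generate_event_train()`) fills the stimulus with
utterances (10–60 s) separated by 500–1100 ms silences, emulating
paragraph structure.  Within an utterance, event timing follows a
pacemaker with four dispersion components, each mapping to a speech
phenomenon:

* a **slowly drifting local rate** `mean_rate · exp(d)`, with `d` an
  AR(1) log-rate process (SD 0.13, per-event coefficient 0.9) —
  articulation rate varies smoothly at the phrase scale;
* small **non-accumulating timing jitter** of on-grid events (SD 6% of
  the local interval) — syllables are produced against the local rhythm,
  so timing errors do not propagate;
* **timing outliers**: 22% of events are displaced with SD 33% of the
  interval — syllables whose acoustic edge falls off the rhythmic grid
  (consonant clusters, reductions);
* **skipped beats**: 12% of grid positions produce no event, with the
  grid phase preserved — reduced or merged syllables.

This architecture was chosen over the simpler alternative of independent
(renewal) inter-event intervals for a substantive reason: a renewal train
whose instantaneous-frequency distribution is as broad as natural
speech's (SD ≈ 0.5 × mean) has an essentially flat spectrum — no energy
concentration at the event rate — and a convolution model driven by it
cannot show the event-rate IEPC peak that slowed natural speech produces.
Natural speech is *locally* quasi-periodic with its broad rate histogram
generated by slow drift and discrete disruptions; the pacemaker encodes
exactly that.  With the default calibration the modal instantaneous event
frequency is 5.7 Hz with SD ≈ 2.9 Hz (regular condition); because the
distribution is right-skewed, the mean of 1/interval sits slightly above
the mode and the realized event count per unit speech time slightly below
it (≈5.4 events/s at the regular rate), as in natural speech.  All
dispersion components scale with `rate_sd/mean_rate`, and `rate_sd = 0`
yields a strict metronome.

The slow condition is canonically built by stretching a regular train
3× in time with peakRate magnitudes scaled by 1/3
(`time_stretch()`), mirroring what uniform time stretching does to the
envelope and its derivative; independent generation from the slow
statistics (1.9 Hz, SD 1.0 Hz) is also available.  Event magnitudes are
log-normal clipped to (0, 1]; only their quantile structure matters
downstream because model inputs are rate-normalized.

`generate_am_waveform()` closes the loop acoustically: a carrier
amplitude-modulated by asymmetric rise/decay bumps (150/300 ms), one per
event, so that envelope extraction and landmark detection recover one
peakRate (at the event time, during the rise) and one peakEnv (at the
bump peak) per well-separated event.  The bump timescales are chosen so
a 10 Hz envelope low-pass leaves the derivative peaks essentially
untouched, keeping the 1/3-magnitude contract of time stretching exact
to within a few percent.

What the generator does *not* emulate: formant structure, pitch,
coarticulation beyond bump overlap, multi-speaker variability, and any
linguistic content.  Passing tests therefore demonstrate correctness of
the analysis machinery and of the models' predictions under speech-like
event statistics — not phonetic realism.

## Signal processing choices

* **Envelope** (`extract_envelope()`): full-wave rectification (absolute
  value), zero-phase 4th-order Butterworth low-pass at 10 Hz, then
  downsampling to 100 Hz, in that order.  Half-wave rectification is
  available as an option.
* **Derivative**: first difference × rate, left-aligned — the simplest
  estimator consistent with a sampled derivative.
* **Landmarks** (`detect_landmarks()`): local maxima with a prominence of
  at least 2% of the series maximum (suppresses the ≈1% ripple of
  zero-phase filtering); peakRate is restricted to maxima of the
  *positive* derivative (amplitude rises).
* **Filter bank** (`tf_decompose()`): band centers log-spaced 0.67–9 Hz
  in 0.1-octave steps; half-widths ±0.1 octave (narrow, spectral
  analyses) or ±0.5 octave (wide, temporal analyses).  Zero-phase
  band-pass filtering is realized spectrally as the squared Butterworth
  magnitude response — mathematically the forward–backward (filtfilt)
  response — because at a 400 Hz rate the lowest bands have normalized
  edge frequencies near 0.003 where transfer-function polynomial
  coefficients are numerically unusable, while the spectral form is exact
  and unconditionally stable.  For each band the order and −3 dB width
  are chosen (smallest feasible order) so the *doubled* response keeps
  passband ripple ≤ 3 dB and attenuation ≥ 24 dB at ±(half-width + 0.5)
  octaves; the design is verified at construction.  Signals are
  reflection-padded 5 s before filtering.  The Hilbert transform is
  applied in the same spectral pass; phase and amplitude are the angle
  and modulus of the analytic signal.
* **Degenerate inputs**: all-flat envelopes yield empty landmark sets; a
  stimulus too short for one inter-event interval yields an empty train;
  a single distinct event magnitude maps to the upper scaling bound.

## Phase statistics

**IEPC** (`iepc()`): the mean resultant length across event-locked
epochs, per band and time point.  Its chance level for $N$ events is the
Monte-Carlo expectation of the resultant of $N$ uniform angles
(`iepc_baseline()`; ≈ $\sqrt{\pi}/(2\sqrt{N})$).  Spectral profiles
average the post-event window matching one cycle at the condition's rate
(0–170 ms regular, 0–500 ms slow); peaks are local maxima of the
3-band-smoothed profile exceeding baseline + 2 SD with a prominence of at
least 2 SD.  Temporal profiles average the bands within half an octave of
the slow rate and flag time points exceeding baseline + 2 SD.  Events
enter the spectral analysis only if not followed by another event within
500 ms, and the temporal analysis only with gaps ≥ 200 ms before and
≥ 1040 ms after (`select_events()`); both thresholds are parameters —
the sources for these analyses quote slightly different gap values
(1000 vs 1040 ms), so no event count is hard-coded anywhere.

**CAC** (`cac()`): the resultant of the phase *difference* between a
neural band signal and the same-band speech envelope across an
utterance; slow utterances are split into three equal parts (averaged
afterwards) to equate time points across rate conditions.

**Cluster inference** (`cluster_perm_test()`): IEPC maps are
baseline-corrected per band (pre-event −400…−100 ms), a pixelwise
one-sample t statistic across replicates is thresholded two-sided at
p < 0.01, suprathreshold pixels form 4-connected clusters scored by
summed t, and the null distribution of the maximum cluster score is
built by sign-flipping the baseline-corrected replicate maps (3000
permutations; cluster threshold p < 0.01).  Sign-flipping is the natural
exchangeability scheme for baseline-corrected one-sample maps.  The
replicate unit is a simulated subject (independent seeds); the family-wise
error of the procedure is verified on null simulations in the test suite.

**Magnitude quantiles** (`quantile_iepc()`): events are split into five
magnitude quantiles (ties resolved stably by event order) and theta-band
(4–8 Hz) IEPC is averaged, per band, over one cycle (1/center) after the
event.  With rate-relative input scaling, a 3×-stretched,
1/3-magnitude slow train lands on the regular train's quantile–quantile
diagonal — the signature of speech-rate normalization.

**Power versus IEPC** (`noise_robustness_sweep()`): the evoked model is
simulated at noise levels 1–10 × signal RMS (20 simulations per level);
per level, theta-band post-event power change and IEPC are converted to
effect sizes (Cohen's dz across simulations).  The sign of the power
contrast depends on the event-selection geometry — enforcing a quiet
post-event gap makes the pre-event baseline the denser neighbourhood —
so robustness comparisons use magnitudes.  The phase measure retains
large |dz| at high noise while the power measure deteriorates quickly.

**Model–data comparison** (`compare_models()`): per-replicate Pearson
correlations of an observed profile with each model's prediction, a
joint regression `observed ~ oscillator + evoked`, and second-level t
tests on the betas across replicates.

## Problem sizes and determinism

Default full runs use a 6.5-min regular stimulus (19.5 min slow) and the
2560-realization ensemble.  The shipped fast profile — used by the test
suite and the reproduction script — halves the stimulus (3.25 min
regular, 9.75 min slow, ≈750 slow events after selection) and uses the
8 × 5 ensemble; at these sizes the discriminating predictions are stable
across seeds while a full comparison completes in minutes on one core.
Every random stage (trains, jitter, noise, permutations) derives its seed
from a single master seed, so identical configurations reproduce
bit-identical summaries.

## Known limitations

* No real sensor geometry: analyses run on one synthetic channel;
  sensor selection, topographies and source modeling are out of scope.
* The acoustic front end is monoband; gammatone or multiband envelopes
  are not provided.
* The oscillator model has no amplitude decay term beyond the limit
  cycle, and no oscillator networks; the evoked model is univariate
  (peakRate only).
* PSOLA-style pitch-preserving time stretching is approximated in the
  envelope domain, which is adequate for envelope statistics but not for
  listening experiments.
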