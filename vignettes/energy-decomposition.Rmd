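---
title: "Deterministic and non-deterministic energy in heart-sound signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic and non-deterministic energy in heart-sound signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgenergy)
```

## The model

A heart-sound recording $x(t)$ is modelled as a repeating beat waveform plus
per-beat components that do not repeat: cavitation transients near a
mechanical valve, murmurs, and broadband noise. Segmenting the recording
into beats, truncating them to a common length $N$ and superimposing them
gives the matrix $p[m, n]$ ($m = 1..HB$ beats). The package decomposes the
signal energy as

$$E_\mathrm{det} = \frac{1}{N}\sum_k |F(p_{ea})[k]|^2, \qquad
  E_\mathrm{total} = \frac{1}{HB}\sum_m \frac{1}{N}\sum_k |F(p[m,\cdot])[k]|^2,$$

with $p_{ea}[n] = \frac{1}{HB}\sum_m p[m,n]$ the ensemble average, and

$$E_\mathrm{nondet} = E_\mathrm{total} - E_\mathrm{det}
   = \frac{1}{HB^2}\sum_{i<j}\sum_n \big(p[i,n]-p[j,n]\big)^2 \ge 0 .$$

The pairwise form is the key property: any waveform common to every beat
cancels exactly, so $E_\mathrm{nondet}$ measures only the non-repeating
content. Two beats $\{y,\, y+\eta\}$ give $E_\mathrm{nondet} =
\lVert\eta\rVert^2/4$; identical beats give zero. Both identities are
asserted exactly in the test suite, and `time_domain_nondet_oracle()` keeps
the pairwise route available as an independent check of the Fourier route
(the two must agree to $10^{-9}$ relative; `beat_energy()` additionally
verifies Parseval's relation on every call).

The decomposition is reported as $100\cdot E_\mathrm{nondet}/E_\mathrm{total}$
percent. On a healthy recording with no true signal of interest, a *lower*
percentage means less residual processing artefact — this is the
figure of merit used throughout.

### Assumptions

* The beat-locked component is genuinely cyclic; valve closure sounds
  qualify, respiratory modulation only approximately.
* Segmentation is approximately correct: every interval contains one beat.
  Timing errors do not invalidate the algebra but inflate
  $E_\mathrm{nondet}$ (see below), which is why alignment matters.
* No low-pass filtering is applied anywhere: the signal of interest is
  typically high-frequency, and filtering would remove it. The price is
  that $E_\mathrm{nondet}$ always contains the noise floor.

## Why beats are aligned, and on what

If one beat is a time-shifted copy of another, $E_\mathrm{nondet}$ acquires
a term $\tfrac12\lVert y\rVert^2(1-\rho(\varepsilon))$ driven by the beat's
autocorrelation $\rho$ at the misalignment $\varepsilon$ — energy of the
*heart beat itself* leaking into the non-deterministic estimate. Since the
heart beat is much louder than any signal of interest, even small
misalignment can dominate the result. The test suite checks that this
leakage grows monotonically with $\varepsilon$ over half a beat period and
that aligning never worsens the percentage on fixtures with imperfect
segmentation.

`align_beats()` therefore locates the S1 peak — the maximum *absolute*
amplitude in the first quarter of the beat (absolute because transducer
polarity is arbitrary; first quarter because S2 can be taller than S1) — and
shifts every beat so its peak coincides with that of the first beat.
`find_s2_peak()` searches the last three quarters instead. After shifting,
all beats are cropped to the sample range covered by every shifted beat.
Cropping, not zero-padding, is deliberate: a zero-filled prefix looks like a
misplaced beat and corrupts the decomposition, whereas cropping only
discards information. The `"best"` analysis mode runs both S1 and S2
alignment and keeps whichever yields the lower percentage.

Beats needing very large shifts are segmentation failures; shifting them
into place would force severe cropping of the whole ensemble.
`remove_misaligned_beats()` drops beats with $|\text{shift}|$ above a
cutoff. No default cutoff is imposed: the sensible value depends on the
signal and should be chosen by inspecting the shift table;
`shift_cutoff_heuristic()` offers $\overline{|s|} + 2\,\mathrm{sd}(s)$ as a
starting point. Shift statistics are reported both as mean/sd of magnitudes
(the convention of shift audit tables) and as the signed sample sd.

## Segmentation

The detector is intentionally simple: a Shannon-energy envelope
($SE(x) = -x^2\ln x^2$, $SE(0)=0$, frame-averaged), an adaptive threshold at
a fraction of the envelope maximum, a refractory period that suppresses the
S2 burst of the same beat, and a median-period pass that resolves any
remaining S1/S2 alternation by spacing. Defaults: 20 ms frames, 10 ms hop,
threshold 0.2, 0.4 s refractory (a 150 bpm ceiling). Sophisticated
segmenters (wavelet-based, ECG-gated, ...) are out of scope by design —
segmentation is treated as a pluggable prerequisite, and externally computed
points are first-class via `load_segmentation()` (0-based sample-index CSV).

All sample coordinates exposed by the package — boundaries, onsets, peak
indices, shifts — are 0-based with half-open intervals, in memory and in
CSV interchange alike.

## Time-resolved decomposition (STFT)

The single-number summary says nothing about *when* in the beat the
non-repeating energy occurs. `time_resolved_energies()` applies the same
decomposition per STFT frame: the deterministic profile is the per-frame
energy of the STFT of the ensemble average, the total profile the mean of
per-beat frame energies, their difference the non-deterministic profile.
Defaults: 1024-sample Hamming window, FFT of the same length, 50% overlap —
at 44.1 kHz this gives ~12 ms frames, enough to separate S1, S2 and
inter-sound intervals. Frame energies are left in window-weighted units;
the constant window factor cancels in the percentages that the profiles are
summarized into (`summed_percent()`), so no window-gain renormalization is
applied. Tail samples not filling a complete window are dropped.

The summed STFT percentage tracks the plain Fourier percentage closely when
beats are long relative to the window (at 44.1 kHz a ~1 s beat is ~43
windows); the residual difference comes from the reduced weight of the
first and last half-window and any dropped tail. The suite requires
agreement within 2 percentage points on 20 synthetic ensembles.

## The synthetic generators

Two generators provide ground truth.

**Analytic sine ensembles** (`generate_sine_ensemble()`): beat $m$ is
$A\sin(\Omega t) + C\sin(\omega_m t + \phi_m)$ over exactly one period
$T = 2\pi/\Omega$, with the "cavitation" tone alternating between two
integer harmonics $\omega_1, \omega_2$ of $\Omega$. The continuous-time
energies have closed forms
$E_\mathrm{det} = \pi(C^2+2A^2)/2\Omega$,
$E_\mathrm{total} = \pi(A^2+C^2)/\Omega$,
$E_\mathrm{nondet} = \pi C^2/2\Omega$ —
notably independent of *which* integer harmonics are used, so the defaults
use desk-scale harmonics (350 and 360) rather than the physically motivated
tens of kilohertz, with identical closed forms and far fewer samples.
Defaults $A=1$, $C=0.2$, $\Omega = 1$ rad/s, $2^{16}$ samples per period;
the discrete pipeline (energies × sampling period) reproduces all three
closed forms within 0.1%, cross-checked against `continuous_energy_oracle()`
(trapezoidal integration, second-order convergent). $\Omega$ is treated as
an angular frequency throughout; a ~1 Hz heart rate corresponds to
$\Omega \approx 2\pi$ rad/s, and the closed forms carry the $1/\Omega$
scaling explicitly.

**Realistic PCG fixtures** (`generate_synthetic_pcg()`): exponentially
decaying tone bursts for S1 (amplitude 1) and S2 (0.6) at 0.1 s and 0.45 s
into each beat, 60 Hz carrier, 20 ms decay, Gaussian white noise
(sd 0.01), beat periods jittered (sd 20 ms) around 1 s, 18 beats, 44.1 kHz
— the recording conditions the pipeline targets. The generator returns the
true S1-onset segmentation, and an arbitrary non-repeating component can be
injected into selected beats. All randomness is seeded through the spec;
identical specs give bit-identical signals.

What the fixtures do *not* emulate: respiratory and autonomic modulation of
beat morphology, baseline wander, sensor transfer functions, and real
cavitation dynamics (the injected burst is a Gaussian-windowed tone). A
green suite therefore demonstrates the correctness of the *algorithm*, not
a clinical performance claim: on real signals the quality of segmentation
and the noise level dominate, and appropriate thresholds for "how much
non-deterministic energy indicates an event" must come from a dedicated
study with the acquisition equipment in question.

## Numerical choices

* DFT convention: unnormalized forward transform, two-sided spectrum, so
  $(1/N)\sum|F|^2 = \sum x^2$ exactly. One-sided spectra would require
  per-bin bookkeeping to keep Parseval and are not used.
* Normalization is peak-absolute (divide by $\max|x|$), idempotent, applied
  once at pipeline start; energy-based normalization would change reported
  energies but not percentages.
* WAV input is integer PCM with full-scale divisor $2^{\mathrm{bits}-1}$,
  so 16-bit round-trips are bit-exact.
* Peak ties break to the earliest index; a flat beat yields the window
  start. Alignment shifts are whole samples only — sub-sample alignment
  would require interpolation whose low-pass character conflicts with the
  no-filtering principle.
* Percentages are rounded to 2 decimals only at the reporting boundary
  (CSV); JSON reports and all internal arithmetic keep full precision.
* Degenerate inputs fail loudly: all-zero signals, un-segmentable
  envelopes, ensembles left with fewer than 2 beats, and shift patterns
  whose common overlap drops below 4 samples are errors, not warnings.

## Problem sizes used in validation

The suite exercises the pipeline at reduced scale chosen for tight
oracles rather than realism: sine oracles at $2^{16}$ samples per period,
random-ensemble identities at up to 4096 samples per beat, fixture
pipelines at 4 kHz sampling with 6–10 beats, and the Fourier/STFT
comparison at 16384-sample beats against the 1024-sample default window
(preserving the beat-to-window ratio regime of 44.1 kHz recordings). The
reference report tables shipped in `inst/extdata/` validate the reporting
arithmetic (percentages recompute from energy pairs; energy triples are
internally consistent; shift-table statistics reproduce).

## Known limitations

* The Shannon-energy detector assumes S1 is the most prominent recurring
  burst; heavily pathological or very noisy recordings should be segmented
  externally.
* Alignment uses a single reference beat (the first retained one). A
  median-reference extension is straightforward but not implemented.
* The non-deterministic energy is a *sum* of signal-of-interest, noise and
  residual misalignment; the decomposition cannot attribute it further.
  The time-resolved profile helps interpretation (misalignment concentrates
  at S1/S2; broadband noise spreads evenly) but is not a classifier.
* Energies of recordings digitized at different rates are comparable only
  after conversion to continuous units (divide by the sampling rate).
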