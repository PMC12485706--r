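---
title: "Methods: spindle detection, thalamic calcium analysis and closed-loop simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spindle detection, thalamic calcium analysis and closed-loop simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlr)
```

spindlr analyses murine polysomnography (EEG/EMG) together with fiber
photometry of thalamic populations — thalamocortical relay neurons (TC),
thalamic reticular nucleus neurons (TRN), and local interneurons of the
ventral posterior nucleus (VPi). This vignette is the package's account of
the models and procedures it implements, the parameters that matter, and the
choices made where the design was genuinely open.

## The spindle detector

Sleep spindles in adult mice are transient 9–16 Hz (sigma band) EEG
oscillations during NREM sleep, 0.5–2 s long, with a waxing-and-waning
envelope. The detector uses three decision series computed from a single EEG
channel:

1. **Relative sigma power** — a short-time Fourier transform of the
   broadband (1–30 Hz) filtered signal over 2 s Hann windows advanced in
   0.2 s steps; each frame's sigma-bin power is divided by its broadband-bin
   power. Threshold: 0.2.
2. **Broad–sigma correlation** — the moving Pearson correlation between the
   broadband-filtered and sigma-filtered signals over 0.3 s windows stepped
   by 0.1 s. When a spindle dominates the broadband trace the two are nearly
   identical. Threshold: 0.65.
3. **Sigma RMS** — moving RMS of the sigma-filtered signal (0.3 s / 0.1 s).
   Threshold: mean + 1.5 × SD of the RMS series, computed over the trace
   passed to the detector. Because the threshold is data-driven, the caller
   should pass the state of interest (NREM) rather than a whole mixed
   session.

Per-sample votes (strict `>` at every threshold, so exact equality never
fires) are summed into a decision vector, smoothed with a 0.1 s moving
average (the soft threshold), and runs with smoothed votes ≥ 2 become
candidate events. Candidates closer than 0.1 s are merged; durations outside
[0.5, 2] s are discarded. Each event is then characterized by eight
features: RMS amplitude, median log10 sigma power of the analytic-signal
envelope, median per-point relative sigma power, peak-to-peak amplitude,
median instantaneous frequency, oscillation count (waveform peaks at least
60 ms apart), duration, and symmetry. Mu events (8–12 Hz, REM) use the
identical machinery with only the event band changed.

Open details fixed here, with rationale:

- **Filter family.** Zero-phase (forward–backward) order-3 Butterworth
  band-passes. Zero-phase filtering is essential: a causal filter would
  shift event boundaries by its group delay and bias every latency estimate.
- **Series-to-sample interpolation.** Frame values carry their window-centre
  time and are step-interpolated onto the sample grid. Step interpolation
  fabricates no sub-window resolution; linear interpolation would
  manufacture threshold crossings between frames.
- **Symmetry.** Defined as the normalized position of the maximum of the
  sigma analytic envelope — the event's most prominent point. A
  peak-prominence rule on raw waveform peaks gives the same answer on clean
  events but is unstable when two peaks have near-equal height.
- **Time convention.** Seconds from trace start; all intervals half-open
  `[start, end)`; epochs are `[t0, t0 + 10)`.

The detector's operating regime is NREM-like EEG: 1/f background plus a
delta oscillation. On pure 1/f noise without delta content the correlation
criterion fires more easily (the sigma band is a larger fraction of the
broadband signal), so background composition matters when constructing
synthetic material.

## Synthetic sessions

The generator produces seeded sessions with ground truth so that every
downstream analysis can be validated by parameter recovery. It emulates:

- a **hypnogram** from a semi-Markov chain on a 10 s epoch grid
  (wake → NREM → {REM | wake}; REM entered only from NREM). Default mean
  dwells: wake 240 s, NREM 180 s, REM 60 s, with a 0.35 NREM→REM entry
  probability — bout statistics in the range reported for adult mice. Bout
  lengths are geometric in epochs, the discrete memoryless choice consistent
  with a semi-Markov chain;
- **EEG** (default 500 Hz): unit-RMS 1/f background (exponent 1) scaled to
  50 µV, a 2 Hz delta oscillation in NREM, a 7 Hz theta oscillation in REM,
  and Poisson-placed spindle bursts in NREM only — constant frequency drawn
  uniformly from 9–16 Hz, duration uniform in 0.5–2 s, Hann envelope, peak
  amplitude 4 × background RMS (the signal-to-noise condition used by the
  recovery suites), 6 events per NREM minute;
- **EMG** (default 500 Hz): Gaussian baseline attenuated in NREM (0.6×) and
  REM atonia (0.4×), with Hann-enveloped movement bursts (gain 10) at
  6/min in wake only;
- **photometry** (default 1 kHz, chosen comfortably above every analysis
  band; the decoding path immediately low-passes and resamples to 50 Hz): a
  latent ΔF/F trace of Poisson calcium transients convolved with a
  rise/decay kernel (0.2 s / 1.0 s), plus state-dependent stimulation
  responses — in NREM an alpha-function transient whose maximum falls
  exactly at the configured rebound latency (default 0.45 s) after pulse
  onset; in wake/REM a negative deflection (suppression). Both channels
  share a slow motion artifact; only the signal channel carries calcium.

Determinism: every generator draws from a sub-stream derived from
(seed, component name), so a (config, seed) pair fixes the session
bit-for-bit, and changing one component does not reshuffle the others.

What the generator does **not** emulate: realistic EEG artifacts (line
noise, electrode pops, eye movement), spindle frequency chirp, coupling of
spindles to slow-oscillation phase, hemodynamic or bleaching trends in
photometry, and inter-subject variability beyond the seed. Passing tests
therefore demonstrate algorithmic correctness under the stated statistical
structure, not performance on real recordings.

## Photometry and EMG preprocessing

ΔF/F uses the two-wavelength convention: the reference (isosbestic-like)
channel is mapped onto the signal channel by ordinary least squares over the
whole session, the fitted trace is the baseline f0, and
`dff = (f − f0)/f0`. OLS over the session is the standard isosbestic
practice; it makes the result invariant to affine rescaling of the
reference and removes shared artifacts up to the fit error.

Movement epochs are labelled from the rectified EMG smoothed with a 0.5 s
moving average; the threshold is median + 7 × MAD of the envelope. Two
ambiguities are resolved and flagged in the API: the MAD is used **raw** (no
1.4826 consistency factor), since it stands in for a robust SD without any
normality claim — `mad_constant` restores the factor if wanted; and an epoch
is "movement" when **any** envelope sample exceeds threshold, the choice
that detects brief twitches a mean-envelope rule would dilute (a documented
alternative would trade sensitivity for robustness).

The two-photon pipeline (background subtraction, single-exponential
photobleach fit, 5-point running mean, ΔF/F against the pre-stimulus mean)
fits the exponential in two passes: frames with strongly positive residuals
(calcium transients) are excluded from the second pass so activity does not
inflate the bleach estimate.

## Event-triggered and spectral analyses

`relative_band_power_trace()` uses the 0.5 s window / 0.1 s step convention
(the detection-internal series uses 2 s / 0.2 s). `event_triggered()`
averages snippets aligned to pulse onsets and reports the latency to the
peak of the mean response in a 0–1 s window (pulses are 0.2 s at up to
1.5 Hz, so responses complete within the cycle).
`cross_correlogram()` correlates a series with the pulse-onset indicator
over ±10 s of lag; entrained spindle activity at 1 Hz produces 10 local
maxima per 10 s of lag, counted with a 0.5 s minimum separation and a
positive-correlation requirement to ignore noise wiggles in the troughs.

## Decoding

Calcium traces are low-passed at 1 Hz (zero-phase) and resampled to 50 Hz;
each 10 s epoch is reduced to five statistics: SD, MAD, IQR, RMS of
successive differences, and relative 0.2–0.5 Hz power over 0.05–3 Hz.
Epochs are labelled positive by any-overlap with ground-truth (or detected)
intervals. Leave-one-subject-out decoding fits, per fold, a standardizer on
the training subjects only, then an elastic-net logistic regression (mixing
0.5). The penalty strength defaults to 1/n_train — the unit-strength
convention of regularized logistic regression — and is deliberately weak:
the point is stable weights, not model selection. ROC curves are averaged
vertically on a 101-point false-positive-rate grid; the reported mean AUC is
the mean of per-fold AUCs, not the AUC of the mean curve. The chance
baseline permutes labels within each subject (preserving class counts
exactly — a permutation, not a resample) and repeats the identical
procedure.

## Closed-loop simulation

`run_protocol()` advances a 10 s rolling buffer epoch by epoch; at each
epoch boundary the stager's state for the completed epoch is compared with
the active schedule window's trigger state, and on a match a 10 s block is
emitted starting at the next sample — so no light ever precedes its trigger
(the real system's hardware latency is unknown; one sample is the minimal
causal choice). Pulsed channels fire `floor(10 × rate)` pulses; inhibition
channels illuminate continuously for the block. The day-in-thirds protocol
triggers on REM, wake and NREM in that order; the day-in-halves protocol
adds continuous inhibition to NREM-triggered stimulation in one half, with
the order reversible to control for circadian drift. The staging CNN of the
original real-time system is out of scope; a pluggable rule-based spectral
stager (EMG envelope for wake, delta/theta ratio for NREM vs REM, with an
intermediate-ratio default to wake) stands behind the same interface, and
the ground-truth hypnogram can be passed instead to isolate protocol logic
from staging error. On default synthetic sessions the spectral stager
agrees with the ground truth on ~98% of epochs.

`compare_conditions()` computes per-subject means of spindles-per-10 s and
the per-event characteristics, after dropping epochs containing any sample
above the 300 × 10⁻⁵ V amplitude cap, and delegates paired comparisons to
the exact Wilcoxon test.

## Behavioural scoring

Go/no-go sessions are scored as performance = (hits + correct rejections) /
all trials, d′ = z(H) − z(FA) and bias = (z(H) + z(FA))/2. Extreme rates
(H or FA ∈ {0, 1}) would send the quantile function to ±∞; they are replaced
by 1/(2N) and 1 − 1/(2N) of the relevant trial count — the standard
correction — and flagged in the output. The disengagement rule truncates a
session at the first run of 10 consecutive unanswered go trials with no
licks on the no-go trials between the first and last go trial of the run.
Training improvement is the difference of metric means across a split
placed at the 4th session from the last.

## Exact tests

The Mann-Whitney U and Wilcoxon signed-rank tests are computed by exact
enumeration whenever the data allow (no cross-group ties / no tied absolute
differences): the full null counting distribution is built by
dynamic-programming convolution, which is arithmetically identical to
enumerating all `choose(n1+n2, n1)` rank arrangements or `2^n` sign
assignments. The test suite verifies this equivalence against literal
brute-force enumeration. Zero differences are dropped before ranking (the
classic convention), which makes the one-sided minimum attainable p exactly
`1/2^n` — the value printed when all paired differences share a sign. Ties
trigger a midrank normal approximation with continuity correction, flagged
in the result. Kruskal-Wallis uses the chi-square reference of
`stats::kruskal.test`; Dunn z statistics carry the tie correction and are
reported unadjusted by default (no multiplicity correction is claimed by
the analyses this mirrors), with `p_adjust` available.

## Numerical choices and problem sizes

- Strict `>` at thresholds; half-open intervals; events sorted by start.
- The recovery suites run at sizes chosen to give stable statistics while
  keeping the full test suite fast: 2–4 min single-state sessions, 20 seeds
  for detector F1 and latency recovery, 100 entrained 10 s blocks for the
  cross-correlogram. These are the package's validation conditions, stated
  here so they can be scaled up when stronger evidence is wanted.
- EDF storage uses 16-bit quantization against per-channel physical ranges
  written in microvolts (the 8-character EDF range fields keep ~6
  significant figures).

## Interfaces

The package is function-first in the tidyverse idiom: data frames in,
tibbles out, `tidy()`/`glance()` on fitted objects, `autoplot()`/`plot_*()`
for figures. File interchange uses EDF (EEG/EMG), CSV (photometry, event
tables, stimulation logs), JSON (ground truth, results) and plain key-value
text (configurations). No shell entry point is provided: the exported
functions and this vignette are the interface, and `scripts/acceptance.R`
shows a complete scripted run.

## Known limitations

- The detector assumes a single artifact-free EEG channel; no multichannel
  consensus, no slow-oscillation or K-complex detection.
- The spectral stager is a stand-in with fixed thresholds tuned to the
  generator's amplitude conventions; on real data its thresholds would need
  calibration, and misclassification feeds directly into protocol timing.
- The exact tests handle ties only approximately; heavily tied data (e.g.
  integer oscillation counts) falls back to the normal approximation.
- Latency estimation reads the argmax of the mean response; multimodal
  responses or drifting baselines would need model-based fitting.
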