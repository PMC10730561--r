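---
title: "Auditory attention decoding by stimulus reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditory attention decoding by stimulus reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aadkit)
```

## The problem

When a listener attends to one of two concurrent talkers, low-frequency
cortical activity phase-locks to the temporal envelope of the attended
speech more strongly than to the ignored one — *neural tracking*. Auditory
attention decoding (AAD) exploits this: from multichannel EEG one
reconstructs an estimate of the attended speech envelope and asks which of
the two candidate talkers it resembles more. `aadkit` implements the linear
backward-model variant of this idea for the dichotic two-speaker paradigm:
an offline decoder evaluated by leave-one-out cross-validation, and a
simulated real-time decoder that operates on a sliding window with
exponential-moving-average (EMA) smoothing of the decision statistic.

## The backward (stimulus-reconstruction) model

Let $R(t, n)$ be the preprocessed EEG of channel $n$ and $S(t)$ the
attended speech envelope, both at the processing rate (64 Hz). The decoder
$D(\tau, n)$ maps time-lagged EEG to a reconstruction

$$\hat S(t) = \sum_n \sum_\tau D(\tau, n)\, R(t + \tau, n),$$

with lags $\tau$ spanning 0–250 ms. Because cortical activity *follows*
the stimulus, reconstructing $S(t)$ uses EEG samples from $t$ to
$t + 250$ ms; positions past the end of a trial are zero-filled so the
reconstruction keeps the trial length. With $X$ the lag-expanded design
matrix ((lags × channels) rows, one column per sample), the ridge solution
is the regularized normal equation

$$D = (X X^\top + \lambda I)^{-1} X S^\top,$$

with $\lambda$ added to the diagonal **un-normalized**, so the default
$\lambda = 10$ has a fixed meaning on z-scored data (the diagonal of
$XX^\top$ is then approximately the sample count). At 64 Hz the 0–250 ms
span gives $\lfloor 0.25 \times 64 \rfloor + 1 = 17$ lags, hence
$17 \times 15 = 255$ weights for the standard montage.

A trial is classified *correct* when the Pearson correlation of $\hat S$
with the attended envelope strictly exceeds the correlation with the
unattended one. Ties and degenerate (zero-variance) reconstructions count
as incorrect — a conservative rule that cannot inflate accuracy.

### Offline evaluation

`loocv_evaluate()` fits one decoder per trial and, for each held-out
trial, averages the weight arrays of all *other* trials elementwise
(equal weights), reconstructs, correlates and classifies. Averaging
decoders rather than predictions matches the protocol this package
implements. Only location-fixed trials enter the offline analysis; a trial
whose presentation side switches mid-way has no single well-defined
attended-side condition. Because each decoder depends only on its own
trial, the package fits all $n$ decoders once and forms each fold's
average as $(\text{sum} - \text{self})/(n-1)$ — algebraically identical to
refitting per fold.

## The simulated real-time decoder

Streaming decoding uses a sliding window of width $W = 15$ s advanced in
steps of $M = 1$ s. Window $i$ ends at $W + (i-1)M$ seconds: the first
window is the first completely filled buffer, so a 60-s trial yields 46
windows. Each window's raw EEG buffer is preprocessed *causally* — the
whole chain is applied to the buffer only, using no samples outside it —
and the matching envelope segments are cut from envelopes that were
preprocessed once per trial and cached, then re-z-scored per window.

Training averages the snippet-wise ridge decoders
$D_i = (R_i R_i^\top + \lambda I)^{-1} R_i S_i^\top$ over every
(trial, window) pair of the training set with equal weights; 14 one-minute
training trials contribute $14 \times 46 = 644$ snippet decoders. At test
time each window's reconstruction is correlated with both speakers'
segments and the two correlation sequences are smoothed independently by
the EMA

$$\hat r_1 = r_1, \qquad \hat r_i = \alpha r_i + (1 - \alpha) \hat r_{i-1},$$

with $\alpha = 0.1$, reset at every trial start. The per-window decision
is the speaker with the larger *smoothed* correlation — the EMA exists to
stabilize exactly this decision — while the *raw* correlations are kept on
the trace because the temporal-sensitivity analysis below must not be
smoothed (smoothing would add its own lag to the measured response time).
A degenerate window yields `NA` correlations, is classified incorrect, and
streaming continues.

## Temporal sensitivity to attention switches

In location-switching trials the attended talker's ear of presentation
switches mid-trial (uniformly in 27–33 s here) while the attended *talker*
stays the same. `temporal_sensitivity()` measures the time from the switch
to the start of the first run of at least 5 consecutive correct 1-s
windows, judged on raw correlations. The 5-s persistence requirement
discards momentary lucky windows; it is implemented inclusively
($\ge 5$ windows at $M = 1$ s), which makes the smallest attainable
response time 1 s. If no qualifying run occurs before the trial ends the
response time is capped at the remaining time (30 s for a mid-trial switch
in a 60-s trial) and flagged.

## Chance levels

For $n$ independent two-alternative decisions the chance level reported by
`binomial_chance_level()` is $100\,k^*/n$ where $k^*$ is the smallest
integer with $P(X \le k^*) \ge 0.95$ under $\mathrm{Binomial}(n, p_0)$
(the inverse-CDF convention). This convention reproduces both standard
protocol bounds exactly — $17/26 = 65.38\,\%$ for 26 trials at $p_0 = 0.5$
and $21/60 = 35\,\%$ for 60 questions at $p_0 = 0.25$ — whereas the strict
tail rule $P(X \ge k) < 0.05$ would give $18/26 = 69.23\,\%$ and disagree
with the first. Accuracies must *strictly exceed* the bound to be called
above chance.

## Preprocessing chain and numerical choices

The chain, in fixed order: common-average re-referencing → zero-phase
band-pass (0.5–8 Hz) → downsampling (125 → 64 Hz) → per-channel z-scoring.
Envelopes are extracted as the magnitude of the analytic signal (Hilbert
transform via FFT), then pass the same band-pass / resample / z-score
steps. Choices a user should know about:

* **Filter design.** Order-3 Butterworth applied forward–backward
  (`signal::filtfilt`), i.e. zero phase. The streaming loop re-filters the
  whole 15-s buffer every second, so zero-phase filtering within the
  buffer is causally realizable in the loop's own terms. At audio rates
  the 8 Hz upper edge sits so low relative to Nyquist that the IIR design
  is numerically unusable; `bandpass()` then decimates internally
  (anti-aliased, delay-compensated), filters at the reduced rate and
  interpolates back — still zero-phase end to end.
* **Resampling.** Rational-factor polyphase resampling (64/125) with a
  windowed-sinc FIR whose group delay is removed, so resampled EEG stays
  time-aligned with the envelopes. Signals are edge-replicated before
  filtering (no boundary droop), and each polyphase branch is normalized
  to unit DC gain so constants are preserved exactly. The resampler is
  applied as a cached sparse banded operator — one matrix multiply for all
  channels of a buffer. Extreme ratios (audio rates down to 64 Hz) run as
  staged integer decimations.
* **z-scoring** uses the population SD (divide by $N$). The convention is
  arbitrary but must be fixed for snippet-level determinism.
* **Edge effects.** Zero-phase filtering of 15-s snippets leaves edge
  transients (≈1–2 s at the 0.5 Hz low edge); these are accepted as-is, as
  part of the method, with no padding or tapering inside the buffer.
* **Non-idempotence of the chain.** An order-3 Butterworth is not a
  brick-wall filter: applying the chain twice re-attenuates content near
  the band edges (≈16 % of signal energy on broadband input), and
  per-channel z-scoring breaks exact common-average zero-mean. The chain
  is therefore *contractive* rather than idempotent — each extra pass
  changes the signal less than the previous one — and the test suite
  checks exactly that.

## The synthetic forward model

Real EEG is not required anywhere: `generate_dataset()` emulates the full
experimental design — 30 one-minute trials, 26 location-fixed and 4
location-switching with switch times jittered uniformly in 27–33 s,
presentation sides balanced 15/15, 15 channels at 125 Hz — from a linear
forward model that is exactly the model class the backward decoder
inverts:

$$\text{EEG}_n(t) = g_a \,(h_n * S_a)(t) + g_u \,(h'_n * S_u)(t) + \varepsilon_n(t).$$

* **Envelopes** are rectified white noise band-passed to 0.5–8 Hz and
  z-scored: non-negative before standardization, with speech-like slow
  modulation, independent across speakers and trials.
* **Kernels** $h_n$ (one per channel) are damped oscillations with
  channel-specific frequency (2–6 Hz), decay (50–150 ms) and phase on the
  0–250 ms support, unit peak — a generic stand-in for cortical temporal
  response functions. The two speakers get independent kernels.
* **Attention is a pure gain difference**: defaults $g_a = 1$,
  $g_u = 0.5$. A 2:1 attended:unattended tracking ratio is a deliberately
  clear but not degenerate margin; equal gains with shared kernels produce
  exact symmetry and hence chance-level decoding, which the tests use as a
  negative control.
* **Noise** defaults to $1/f$-shaped (EEG-like) with SD 1 relative to the
  unit-variance convolved streams. Trials are synthesized at 64 Hz and
  upsampled to 125 Hz so the pipeline's real resampling path is exercised.
* **Switching trials** contain an attention lapse of $L = 8$ s starting
  at the switch: while the listener reorients, the *roles* of the two
  streams swap — the competing speaker transiently receives the attended
  processing (kernel and gain) and vice versa — after which tracking of
  the (unchanged) attended talker resumes. When both speakers share one
  kernel this reduces to a pure gain swap; with per-speaker kernels the
  role swap is essential, because a gain swap alone leaves the decoder
  (which separates speakers by kernel, not amplitude) undisturbed.
  $L = 8$ s is a demonstration default chosen to be of the same order as
  response times reported for real listeners; it is a dial of the
  generator, not a claim about listeners. Note one consequence of the
  protocol geometry: an 8-s lapse never supplies the *majority* of a 15-s
  analysis window, so on clean synthetic data the raw per-window decisions
  stay correct throughout the lapse and the temporal-sensitivity statistic
  reports its 1-s floor. Real listeners show longer response times because
  their disruption is not a bounded, cleanly-delimited interval. Lapses
  approaching or exceeding the window width do flip windows and drive the
  statistic through its full range, which is how the metric's tests
  exercise it.

### What the synthetic model does and does not show

Passing the synthetic suite shows the pipeline inverts its own generative
model correctly — perfect accuracy in the noise-free 4:1 regime, chance
under exact symmetry, reproducibility from a seed. It does **not**
calibrate real-world performance: real EEG has volume conduction
(correlated channels), artifacts, nonstationarity and far lower effective
SNR. Two consequences observed in this package's own experiments are worth
recording. First, with independent per-channel noise the ridge decoder
behaves like a matched filter across 255 lag-channel regressors and stays
at ceiling accuracy even for noise SDs far above the signal scale (the
noise grid 0–4 leaves accuracy at 100 %); genuine degradation appears only
in a harder regime — shared kernels, a 10 % gain margin, broadband noise,
short trials — which the unit tests exercise. Second, published
real-EEG figures for this protocol (offline ≈ 90.6 %, real-time ≈ 78.4 %,
sensitivity ≈ 8 s across nine subjects) depend on those subjects' brains
and cannot be reproduced from synthetic data; `aad_reference()` carries
them for context only and every report labels them as such.

## Problem sizes used by the shipped experiments

The package's own test suite and the acceptance script choose problem
sizes once, as a balance between statistical clarity and desk-scale
runtime, and state them here: the headline runs use the full design
(30 × 60-s trials, 14-trial real-time training, 46 windows per trial); the
noise sweep uses 12 fixed trials of 30 s per seed with 5 seeds per noise
level, offline accuracy only; property tests use 4–8 trials of 16–20 s.
Module-level oracles (ridge vs brute-force normal equations) run on ≤ 5
channels, ≤ 6 lags, ≤ 300 samples, 100 random instances at 1e-8 relative
tolerance.

## Known limitations

* The lag convention resolves an ambiguity in the usual notation
  ($R(t - \tau)$ written next to "0–250 ms post-stimulus"): this package
  uses EEG at $t + \tau$, the standard stimulus-reconstruction convention.
* Offline correlations include the zero-filled lag edge at the trial end;
  with 250 ms of edge in a 60-s trial the effect is negligible but it is
  part of the definition used.
* Whether envelope z-scoring should be per-trial or global is answered
  per-trial here, to match the per-snippet behaviour of the streaming
  path.
* No artifact rejection, channel interpolation or line-noise handling:
  none are part of the modeled chain.
* EDF export is 16-bit with an 8-character physical-range field; round
  trips are exact only to ≈ 1e-4 relative.
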