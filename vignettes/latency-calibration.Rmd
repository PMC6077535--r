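---
title: "Latency calibration for stimulus-on-device hybrid BCIs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latency calibration for stimulus-on-device hybrid BCIs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcicalib)
```

## The problem

In a stimulus-on-device (SoD) brain-computer interface the visual stimuli
are embedded in the controlled appliances themselves and triggered over a
wireless link. The EEG recorder logs the moment the coordinator *sent* each
trigger, but the LED flashes only after a node-specific transmission delay.
A P300 decoder that epochs the EEG relative to the trigger therefore sees
the response later than expected — by the wireless delay plus whatever the
subject's own P300 latency deviates from the nominal 300 ms. Both offsets
shrink or shift the usable feature window, and the damage grows as the
epoch gets shorter.

The same delay, however, is visible in a second signal: a steady-state
visually evoked potential (SSVEP) driven by a 16 Hz flicker on the same
node is phase-locked to the *actual* flicker, so its phase lag against a
zero-delay reference measures the delay directly. `bcicalib` implements the
resulting calibration scheme:

1. **Registration** — for each node, flicker blocks under four stimulation
   phases (0, pi/2, pi, 3pi/2) give a four-component phase-lag vector, and
   an oddball training block gives a measured P300 latency centroid. An
   interval type-2 fuzzy logic system (IT2FLS) trained by an artificial
   bee colony (ABC) maps lags to centroids.
2. **Operation** — epochs for classification are extracted in windows
   *centered* on the predicted centroid instead of a fixed interval
   starting at trigger + 300 ms; a CCA spatial filter and an RBF-SVM then
   classify target vs nontarget, and the per-trial argmax of decision
   values selects one of the four nodes.

## Timing model

A 16 Hz flicker has period T = 62.5 ms, and a sinusoidal flicker starting
at phase zero peaks a quarter period after onset, so the zero-delay
reference response peaks at `t_ref` = 15.625 ms. The phase lag of an
observed response peaking at `t_res` is

theta = (t_res − t_ref) / T × 360°, wrapped into [0°, 360°).

A transmission delay of one sample of the phase chart — 15.625, 31.25,
46.875 ms — maps to 90°, 180°, 270°. The wrap matters: phase is circular,
so the mapping from delay to lag is one-to-one only while the total delay
(transmission delay plus the subject's own SSVEP latency) stays below one
period, 62.5 ms. The calibration model is trained per subject on the
wrapped chart, so a wrap inside one subject's registration is learnable;
the pooled *linear* correlation analysis (`correlation_experiment()`)
instead enforces the no-wrap regime, because Pearson's R on a circular
variable is otherwise uninterpretable.

`estimate_response_peak()` measures `t_res` as the phase of the Fourier
component at exactly 16 Hz over the 5 s block (an exact DFT bin: 80 whole
cycles), on the mean of O1/O2. A time-domain peak pick would need
interpolation — 16 Hz is 31.25 samples per cycle at 500 Hz — while the
Fourier bin is exact and noise-optimal for a sinusoid in white noise. A
cross-method test checks it against cycle-folding plus quadratic-peak
interpolation on noiseless signals.

## The fuzzy calibration model

The regressor is a four-input interval type-2 fuzzy system with three
Gaussian membership functions per input. Each membership function has an
*uncertain mean* `[m_low, m_high]` with a shared sigma: the upper grade is
1 inside the band and the nearest-edge Gaussian outside; the lower grade is
the farthest-edge Gaussian. The footprint of uncertainty absorbs the
measurement noise of the phase estimates.

The rule base is diagonal — rule j combines membership function j of all
four inputs under a product t-norm. A full 3^4 grid would have 81 rules and
more than 500 free parameters, far too many to fit from the K = 16 pairs a
registration session yields; the diagonal base keeps the parameter vector
at D = 4×3×3 + 3×2 = 42 while still covering the one-dimensional manifold
that the four lags trace as the delay varies. Rule consequents are
intervals `[c_l, c_r]` in ms; center-of-sets type reduction produces the
output interval `[y_l, y_r]`, and the crisp prediction is its midpoint.

Type reduction follows the Karnik–Mendel procedure. The optimum has
switch-point structure in c-sorted order, and with only three rules the
package searches all n + 1 integer switch points outright rather than
iterating: the result is exact, involves no tolerance, and avoids the
spurious fixed points the classic iteration can reach when lower firing
grades underflow to zero. A brute-force enumeration over all 2^n firing
vertices serves as an independent oracle in the tests.

## Training by artificial bee colony

Each food source is a 42-vector decoding to a full parameter set; decoding
repairs order constraints (sorts each `(m_low, m_high)` and `(c_l, c_r)`
pair) so the search space stays a box. Fitness is `1 / SSE` over the
training pairs, capped at 1e12 when the SSE drops below 1e-12; a pair on
which no rule fires contributes the squared width of the consequent box as
a penalty.

The colony runs the standard three phases — employed (one-coordinate
neighbor moves with greedy acceptance), onlooker (roulette selection
proportional to fitness), scout (at most one per cycle: the most stagnant
source beyond the `limit` is resampled uniformly) — with the global best
kept outside the colony, so the best-fitness history is monotone by
construction. Defaults are a colony of 30, limit 50, and 500 cycles with
means bounded to [0, 360]°, sigmas to [5, 120]°, and consequents to
[200, 600] ms; on the noiseless K = 16 recovery problem this configuration
reaches an evaluation RMSE of a few milliseconds in under a minute on one
core. Data are split 60/40 into training and evaluation instances, the
convention of the registration protocol; the split is *stratified by node*,
because with only a handful of pairs per node a plain random split can
orphan an entire node into the evaluation set, leaving the model untrained
on that input region — every node contributes at least one training pair.
Note also that the evaluation RMSE is computed against held-out *measured*
centroids, which carry their own measurement noise, so it upper-bounds the
true prediction error.

## Signal processing choices

* **Filtering**: a 4th-order Butterworth band-pass design, 4–20 Hz, applied
  forward–backward with 1 s odd-reflection padding. Zero phase is mandatory
  because latency is the measurand; the order-4 design keeps the 16 Hz
  passband loss under 5% in amplitude after the forward–backward pass while
  attenuating 2 Hz drifts by more than 99%.
* **Epoching**: 0-based indices, half-open windows, sample = floor(t×rate).
  Feature epochs are cut from a 0–600 ms base window around each flash.
* **Averaging before downsampling**: epochs are averaged within their
  (block, node) group at 500 Hz and only then decimated by 8 to 62.5 Hz.
  The band-pass has already confined the signal below the decimated
  Nyquist (31.25 Hz), so plain phase-0 decimation is alias-free.
* **Centroid**: the maximum of the P3/Pz/P4-mean waveform in a 200–500 ms
  search window, refined to the amplitude-weighted mean time over the
  contiguous run of samples at or above half the peak. For a symmetric
  template this equals the peak; under noise it degrades gracefully. A
  flat or non-positive window raises a typed no-P300 condition. Two
  robustness measures stabilize it at realistic SNR: the waveform is first
  smoothed with a zero-phase Gaussian kernel (SD 12 ms — the P300 carries
  its energy well below the 20 Hz band ceiling, so smoothing removes
  narrow in-band noise peaks without shifting a symmetric bump), and
  during registration each block/node centroid is searched within ±70 ms
  of the grand-average-of-all-targets centroid, whose far larger trial
  count makes it a robust subject-level anchor.
* **Channel roles**: O1/O2 feed the SSVEP estimate, P3/Pz/P4 the latency
  centroid; the montage lists all five without assigning roles, so this
  assignment is a package choice.
* **Spatial filter**: canonical correlation between the concatenated
  single-trial target epochs and their tiled grand average, solved from the
  two mirrored eigenvalue problems with a relative ridge (1e-6 × trace/q)
  added only when a covariance block is near-singular. One component is
  kept by default. The filter is fit on registration-session target epochs
  and frozen — never refit on operation data, so no leakage into testing.
* **Classifier**: soft-margin RBF-SVM (libsvm via e1071), `(C, gamma)`
  selected by stratified 5-fold cross-validation over
  C ∈ {0.1, 1, 10, 100} × gamma ∈ {0.001, 0.01, 0.1, 1} on the training
  session only. Trials are scored by the argmax of decision values across
  the four nodes, ties to the lowest node id.
* **ITR**: Wolpaw bits per selection,
  B = log2 N + P log2 P + (1−P) log2((1−P)/(N−1)), with the P ∈ {0, 1}
  terms taken as continuity limits, scaled by a configurable selection time
  (default 3 s ≈ 4 stimuli × 5 repetitions × 125 ms plus the epoch tail).

## What the synthetic generator emulates

No public recordings exist for this paradigm, so the generator is
first-class, tested code that produces sessions with ground truth:

* **Background noise**: 1/f-shaped noise plus a white floor, mixed 0.8/0.6
  so the total SD equals `noise_sd` (default 15 µV), per channel.
* **SSVEP**: a 16 Hz sinusoid (gain 3 µV on O1/O2, second harmonic at
  ratio 0.25) delayed by the stimulation phase offset plus the node delay
  plus the subject's SSVEP latency.
* **P300**: a positive Gaussian bump (SD 40 ms, default amplitude 6.5 µV on
  P3/Pz/P4, half on O1/O2) at `base latency + actual flash delay + jitter`
  for target flashes only. Trial-to-trial latency jitter has SD 20 ms.
* **Wireless timing**: markers record coordinator send times; each flash
  lands after a per-flash delay drawn from a Gaussian around the node's
  transmission delay, truncated at zero (a trigger cannot arrive early).
  All delay lives in the signal, which is precisely the desynchronization
  the method addresses.
* **Subjects**: base latency ~ 345 ± 30 ms across subjects, amplitude
  6.5 ± 1 µV, and a shared visual-latency component that shifts the SSVEP
  and the P300 together. That shared component is what makes the phase lag
  predictive of the latency centroid *across* subjects; within a subject
  the node delays do the same job. The population is deliberately
  late-latency: a window anchored at the nominal 300 ms must routinely
  miss response energy for the calibration to matter at all epoch lengths,
  which is the operating regime the reference comparisons exhibit.
  Amplitude, noise, and jitter defaults place five-repetition selection
  accuracy in the 70–90% band typical of four-choice P300 interfaces — a
  saturated generator would hide any window-placement effect, and a
  floored one would hide everything.

What the generator does *not* emulate: ocular and muscle artifacts,
electrode drift and impedance changes, non-Gaussian P300 shapes
(P3a/P3b decomposition), latency-amplitude coupling, radio packet loss,
and ambient-light effects on stimulus contrast. Passing tests therefore
show the pipeline is correct and that the calibration effect follows from
the stated timing model — not that the effect size matches any particular
real cohort.

## The experiment grid

`run_full_experiment()` simulates n subjects (default 5, mirroring the
reference cohort), each with one registration session (4 protocol repeats,
so K = 16 training pairs from 4 nodes), a training operation session, and
a test operation session, then sweeps epoch lengths
{160, 140, 120, 100, 80, 60} ms under calibrated and fixed window
placement — 12 grid cells per subject. Fixed windows are
`[t_s + 300, t_s + 300 + L]`; calibrated windows are
`[t_c − L/2, t_c + L/2]`. Default node delays are the four reference
conditions 0, 15.625, 31.25, 46.875 ms.

The acceptance checks run this machinery at reduced problem sizes chosen to
keep each check inside a desk-scale budget while leaving the effect
detectable: 10 subjects × 30 trials for the calibrated-vs-fixed comparison
(delays 20–60 ms, 250 ABC cycles), and a delay sweep {0, 15, 30, 45} ms at
80 ms epochs with 3 seeds per delay. Table-mean checks use
round-half-away-from-zero at one decimal; two cells of the published
reference table are inconsistent with the rounding of their own
per-subject entries (their recomputed means sit 0.1 higher) and are
flagged as rounding anomalies rather than matched exactly.

## Numerical and degenerate-input conventions

* Phase lags always live in [0°, 360°); angle averaging across protocol
  repeats is circular (resultant-vector), not arithmetic.
* Type reduction raises a typed condition when no rule fires (all upper
  grades zero) rather than returning a silent fallback.
* `sample = floor(t × rate)` everywhere; windows are half-open, so
  adjacent windows never share a sample.
* An SSVEP segment must span an integer number of flicker cycles (exact
  DFT bin) and clears an absolute amplitude floor of 0.05 µV, below which
  a typed no-SSVEP condition is raised.
* Decoded ABC positions are repaired (pair sorting, sigma floor) instead
  of rejected, keeping the search space box-shaped.
* JSON serialization uses 17 significant digits, so parameters, filters,
  and records round-trip bit-exactly.

## Known limitations

* The diagonal rule base cannot represent mappings that need interactions
  between non-matching membership functions of different inputs; for this
  paradigm the four lags are redundant encodings of one delay, so the
  restriction is harmless, but the class is not a universal approximator
  at D = 42.
* Calibration helps only when the fixed window actually misses response
  energy — with nominal-latency subjects and delays well under the epoch
  length, calibrated and fixed placement coincide and the gap is near
  zero.
* Delays at or beyond one flicker period (62.5 ms) alias in phase; the
  package assumes sub-period delays and documents the wrap rather than
  attempting to unwrap across nodes.
* The SVM decision-value argmax assumes exactly one cued node per trial;
  no-control (idle) states are out of scope.
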