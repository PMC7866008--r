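---
title: "Classifying chest-compression depth from accelerometer waveforms"
author: "ccdnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying chest-compression depth from accelerometer waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During cardiopulmonary resuscitation (CPR) each chest compression should
reach a depth of roughly 5--6 cm at a rate of 100--120 compressions per
minute. Compressions shallower than 5 cm or deeper than 6 cm are clinically
abnormal, and portable training devices try to detect them in real time. The
traditional route measures depth by double integration of a chest-mounted
accelerometer signal, which accumulates sensor error and drift. `ccdnet`
implements the alternative route: treat each compression's acceleration
waveform as a pattern and classify it directly as correct-depth (label 1) or
abnormal (label 0) with a small one-dimensional convolutional network,
keeping the double-integration estimate only as a baseline for comparison.

The package covers the whole chain: a synthetic accelerometry generator
(manikin recordings of this kind are not publicly deposited, so the
generator stands in for them), noise filtering, pulse recognition and
segmentation, max-value alignment to a fixed-length network input, the CNN
architectures with training and evaluation, and an end-to-end pipeline.

## The synthetic-data generator

`simulator_config()` / `simulate_trace()` emulate a single-axis
accelerometer strapped to the sternum of a manikin:

* **Sampling**: one sample every 5 ms (200 Hz).
* **Compression schedule**: each compression draws its instantaneous rate
  uniformly from 100--120 per minute; the compression waveform occupies the
  period minus a quiescent inter-pulse gap drawn from 0.08--0.18 s, giving
  pulse widths of roughly 0.32--0.52 s.
* **Pulse shape**: a raised-cosine (half-cycle) deflection from the
  static-gravity baseline. No analytic form of the true waveform is
  published; the raised cosine is smooth and unimodal, which is what the
  filtered recordings look like, and its single amplitude parameter gives a
  clean handle on depth.
* **Amplitude map**: linear, 0.2 m/s² per mm of depth, so depths of
  35--75 mm produce peaks of 7--15 m/s² — comfortably above the
  detection threshold (about 2.45 m/s² at the default settings) for
  every legitimate pulse, shallow or deep. Because the pulse duration varies
  while amplitude codes depth, plain double integration of the template does
  *not* return the labelled depth in physical units; the integration
  baseline therefore carries one calibration factor fitted on training data
  (see below), which is how the traditional method is deployed in practice.
* **Depth mixture**: insufficient (35--50 mm), correct (50--60 mm,
  boundaries labelled correct) and excessive (60--75 mm) classes with
  default weights 0.25 / 0.5 / 0.25, mirroring a deliberately balanced
  training collection.
* **Disturbances**: white noise (sd 0.3 m/s²), sparse "hammering" spikes
  (4 per minute, 10--20 m/s²), and optionally a random-walk baseline
  drift (`drift_rw_sd`, off by default) for studying integration drift.

Ground truth (start/end/peak sample, depth, label) is recorded *before*
noise is added, so segmentation recall is well defined. All randomness flows
from the single `seed` field; the pulse schedule is drawn before the noise,
so the same seed with and without noise yields identical pulse placement.

What the generator does **not** emulate: mattress compliance, sloped
surfaces, multi-axis coupling, sensor quantization, or operator-specific
waveform idiosyncrasies. Tests passing on synthetic data show that the
pipeline's machinery is correct and self-consistent, not that its accuracy
numbers transfer to recordings from real devices.

## Filtering

Two filters are applied in a fixed order (`apply_filters()`):

1. **Low-pass amplitude-controlled filtering.** Samples deviating from a
   running-median baseline (1.5 s window) by more than the clamp — default
   3× the MAD-based robust deviation of the trace — are clipped to the clamp
   boundary, suppressing spike anomalies; then a first-order low-pass
   recursion with a 15 Hz cutoff is run forward and backward over the
   signal. The zero-phase (forward--backward) application matters: a causal
   single-pole pass delays the signal by about two samples, which biases the
   cut boundaries and can add more lag error than the noise it removes.
   15 Hz keeps the compression fundamental (≈2 Hz) and its first harmonics
   untouched while roughly halving wide-band noise.
2. **Median filtering**, sliding window of 5 samples (25 ms) with replicate
   padding, removing residual impulsive points at negligible cost to the
   pulse peak.

Neither cutoff, clamp nor window is prescribed by prior work beyond
qualitative statements; all three are configuration values.

## Pulse recognition and normalization

`detect_pulses()` implements a dual-sliding-window threshold procedure: a
window over the raw samples (A) and one over the filtered samples (B).

* The **static gravity value** is estimated (`estimate_static_gravity()`)
  as the median of the quiescent portion of the signal, located through the
  mode of a kernel density estimate — the quiescent samples concentrate in a
  narrow band, while compression samples spread across the pulse amplitude,
  so the density mode is a reliable anchor even at high duty cycles where
  the plain median would sit inside the pulse lobe.
* A candidate opens when the filtered deviation from the gravity value
  exceeds **α% of it** (default α = 25, within the empirical 21--32 range).
* The **cut start** is the last sample within α/2% of baseline before the
  crossing, refined by walking to the local minimum of the deviation; the
  refinement recovers the true pulse onset exactly on noise-free signals,
  where the fixed α/2 rule alone would clip about 10% of the pulse on each
  side. Window B supplies this point; if B carries no sub-threshold sample
  in the look-back window, the raw window A is consulted. The **cut end** is
  found symmetrically after the deviation returns below α/2%.
* Three restrictions then decide whether the candidate is a compression:
  (i) duration within 0.25--0.60 s (from the 100--120/min rate), (ii) peak
  deviation at least `min_amplitude` (default 3 m/s²), and (iii)
  unimodality — exactly one dominant extreme, where local maxima above half
  the peak are merged unless the valley between them drops below 80% of the
  lower one. The prominence rule stops residual noise ripple on a broad
  pulse top from masquerading as a double compression.

Each kept pulse is normalized by **max-value alignment**
(`align_and_pad()`): the baseline is subtracted, the sample of maximum
absolute deviation (first occurrence on ties) is placed at position
`floor(0.75 L)` of a length-`L` zero vector — 75% of the points to its
left, 25% to its right — and uncovered positions stay exactly zero, with
overhanging samples truncated. `L` is 70 by default (the classical
"effective sampling point" count) and 72 for the CPCNN architectures, whose
printed flatten sizes force the distinction.

## The 1D-CNN architectures

All networks are stacks of same-padded stride-1 1D convolutions, each
followed by a rectifier, optional batch normalization (after the
activation), and length-2 max pooling with floor division; then two hidden
fully connected layers and a 2-class softmax. Dropout (0.5) sits after the
last convolution block and after the first fully connected layer.

| name | input | conv channels (kernel) | FC | flatten | parameters |
|------|-------|------------------------|----|---------|-----------|
| `lenet5_1d` | 70 | 32 (5), 64 (5) | 128, 64 | 64×17 = 1088 | 158,274 |
| `cpcnn4` | 72 | 32 (7), 64 (5), 128 (3) | 128, 64 | 128×9 = 1152 | 191,234 |
| `cpcnn5` | 72 | 32 (11), 64 (7), 128 (5), 196 (3) | 128, 64 | 196×4 = 784 | ≈240,198 |
| `alexnet_1d` | 72 | 32 (11), 64 (5), 128 (3), 256 (3) | 1024, 128 | 256×4 = 1024 | ≈1.3 M |

Parameter counts exclude batch-norm scales/shifts (the convention of the
printed totals); `count_parameters()` can include them. Same padding plus
floor pooling is the combination that reproduces the printed flatten sizes
1088 and 1152, and hidden widths 128/64 are adopted for the CPCNN variants
by analogy with the LeNet row. The `cpcnn5` flatten (196×4 = 784) cannot be
reconciled with its sometimes-quoted "896"; with 196 channels and integer
pooled lengths no such factorization exists, so the 784-flatten spec here
makes no claim to match that figure. `alexnet_1d` is a best-effort extra
with the same caveat.

The layers (im2col convolution, pooling, batch norm, dropout, dense,
softmax) and their backward passes are implemented in the package directly
— verified against finite-difference gradients in the test suite — and
training uses mini-batch gradient descent with the adaptive-moment (Adam)
optimizer, learning rate 10⁻³, batch size 40. The loss is the standard
binary cross-entropy, −1/N Σ[ŷ log y + (1−ŷ) log(1−y)], applied to the
class-1 softmax probability. Training, initialization, batch order and
dropout masks all flow from one seed, so runs are bit-reproducible.

## Evaluation

`confusion()` counts with class 1 (correct compression) as positive;
`accuracy()` is (TP+TN)/total and `f_score()` the harmonic mean of
precision and recall, fixed to 0 when TP = 0. `roc_auc()` sweeps the unique
scores as thresholds and integrates trapezoidally, which equals the
normalized Mann–Whitney U statistic (ties counted half); the test suite
checks that identity against a pairwise brute-force oracle.

`integrate_depth()` is the traditional baseline: remove the baseline,
integrate the acceleration twice with the trapezoidal rule, take the peak
displacement magnitude as depth, and label it against the 50--60 mm band.
In the pipeline the baseline route gets one scalar calibration fitted on
the training split (median ratio of true to integrated depth) — the
analogue of the device calibration the traditional method requires — and is
still handicapped by pulse-duration variability and noise drift, which is
precisely the weakness the classification route sidesteps.

## The pipeline and the standard benchmark

`run_pipeline()` chains everything: simulate → filter → segment → split →
train → evaluate. The default configuration builds 937 labelled pulses of
which 471 are correct-depth, splits them 680 (train) / 120 (test) / 137
(validation) stratified by label, trains `cpcnn4` for 300 iterations at
batch size 40, and reports accuracy, F-score, AUC, confusion counts, and
the calibrated integration baseline on the test partition. One global seed
fans out deterministically to the simulation, split and training stages.

Problem sizes in the test suite are deliberately modest — 20–60 s traces,
datasets of 50–404 pulses, 40–300 training iterations — chosen so the whole
suite exercises every path in a few minutes while leaving the statistical
checks (segmentation recall/precision over 50 seeded traces, five-seed
training medians, 2000-sample AUC) well-powered.

## Numerical choices and degenerate inputs

* Ties in max-value alignment and max pooling resolve to the first
  occurrence — deterministic and order-stable.
* Indices inside R objects are 1-based inclusive; exported annotation files
  use 0-based half-open intervals, converted at the IO boundary.
* Boundary depths 50 mm and 60 mm are labelled correct (inclusive band).
* A constant trace has zero MAD; the clamp then disables itself and the
  gravity estimate falls back to the median.
* Cross-entropy clamps probabilities to [ε, 1−ε], ε = 10⁻¹², and warns
  when a saturated probability disagrees with its label.
* Training aborts with diagnostics if the loss becomes non-finite.
* `make_dataset()` bounds its simulation attempts and raises a generation
  error if the requested class balance is unreachable.

## Known limitations

* The synthetic generator is the only data source wired in; the waveform
  template and amplitude map are choices, not measurements, so accuracy
  figures obtained on it say nothing quantitative about real recordings.
* The segmentation start/end refinement assumes pulses return near baseline
  between compressions; leaning on the chest (incomplete recoil) would
  violate that.
* Batch processing only — no streaming or embedded-latency considerations.
* The boundary depths near 50 and 60 mm are intrinsically hard for the
  classifier on realistic mixtures: amplitudes on either side of the
  boundary differ by arbitrarily little, which caps achievable accuracy
  below 1 on the default (non-separable) benchmark.
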