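---
title: "Methods: equine ECG filtering, S-peak detection and beat classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equine ECG filtering, S-peak detection and beat classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(equibeat)
```

This vignette documents the models and procedures implemented in
`equibeat`, the assumptions behind them, the tunable parameters and
their defaults, the numerical choices made where the design was open,
and what the simulator-based tests do and do not demonstrate about
real recordings.

## The problem

Horses have a different cardiac conduction system from humans, which
changes the surface ECG morphology: the ventricular depolarization
appears as a deep **negative S deflection** (recorded with the
modified base-apex configuration at 500 Hz) rather than the tall
positive R of human leads, T waves are proportionally much larger, and
resting rates are low (25–50 bpm) while exercise rates reach 240 bpm.
Software built for human ECGs mis-detects on such signals, so the
pipeline here is equine-specific at each stage while remaining able to
process human recordings (for cross-species transfer learning).

Beats are classified into four classes by underlying mechanism:
normal (N), atrial premature contraction (APC; near-normal QRS, early
timing), ventricular premature contraction (VPC; widened abnormal QRS,
early timing, compensatory pause) and artefact (A; non-cardiac
transients).

## Baseline removal and denoising

Baseline wander (breathing/movement, < 1 Hz) is estimated by a
cascade of two running medians and subtracted. The first window
(`median_width_1`, default **0.200 s**) is wider than any P wave or
QRS complex, so those deflections are flattened while the drift
passes; the second (`median_width_2`, default **0.600 s**) likewise
removes T waves. What survives both medians is the baseline. Windows
are converted to samples, forced odd, and the signal is reflect-padded
so output length equals input length. Because the median of a
constant is that constant, the operator maps constants to zero and is
shift-equivariant — both are tested.

Residual high-frequency noise is suppressed by multilevel DWT
thresholding. Two wavelets are plausible defaults for ECG denoising;
the package defaults to **Daubechies-8** with **Coiflet-2**
selectable (`filter_config(denoise_wavelet=)`). The decomposition
depth defaults to **4 levels** at 500 Hz, which places the discarded
detail scales above roughly 15 Hz while the QRS energy is retained.
The threshold value is not fixed a priori; the default is the
universal threshold σ·√(2·log n) with σ estimated from the median
absolute deviation of the finest detail scale, applied **softly** per
level. Hard thresholding and a fixed threshold are available; a fixed
threshold of zero reproduces the input to floating-point accuracy
(the transform pair is exactly orthogonal, verified to ~1e−15 in the
tests). The periodized orthogonal DWT/SWT and the db8/coif2/sym4
filter banks are implemented inside the package; the filters are the
standard published orthonormal coefficients.

## S-peak detection

Detection operates on the filtered detection lead (lead II by
default). The statistic is the **squared stationary-wavelet detail
coefficient at scale 4** (cd4²) with a **Symlet-4** wavelet, whose
shape matches the equine QRS; at 500 Hz scale 4 straddles the QRS
band (~15–30 Hz) and rejects most P/T energy. The undecimated
transform keeps coefficients sample-aligned; the implementation
compensates the cascade's group delay so a deflection at sample *i*
produces its coefficient response at *i* (tested to ±40 ms).

A relative maximum of cd4² is accepted as a beat when it exceeds the
adaptive threshold *t_QRS* = `threshold_factor` × the rolling mean of
the last `maxima_window` relative maxima — with the defaults 1.25 and
200, exactly (1.25/200)·Σ of the last 200 maxima. If several maxima
exceed the threshold within one refractory span (default **0.200 s**,
the shortest equine ventricular effective refractory period), the
largest is selected. Design choices where the procedure was open:

* **Relative maxima** are strict local maxima with a 10 ms minimum
  separation, suppressing plateau duplicates.
* **Every** relative maximum updates the rolling history, accepted or
  not — the threshold adapts to the coefficient background, which
  also means high-amplitude artefacts briefly raise it (a blanking
  effect visible as missed beats right after artefact bursts).
* **Warm-up**: before 200 maxima exist the mean is taken over what is
  available, seeded with the global cd4² maximum of the first second,
  so the first beats are detectable. The threshold compared against a
  maximum is computed from the history *before* it.
* **Peak refinement**: detection happens in the coefficient domain,
  but the reported index is the extremum of the filtered signal
  within ±40 ms of the coefficient maximum — the physical S (minimum,
  equine) or R (maximum, human) peak; `polarity = "auto"` takes the
  largest absolute deflection. Refinement can shrink an inter-peak
  gap, so the refractory rule is re-enforced afterwards (the
  larger-coefficient peak wins).

A classic **Pan-Tompkins** detector (5–15 Hz band-pass, five-point
derivative, squaring, 150 ms moving-window integration, adaptive
signal/noise thresholds, 200 ms refractory; no search-back) serves as
the baseline. On equine records with tall, relatively peaked T waves
its amplitude-based threshold mistakes T waves for QRS complexes —
the simulator reproduces this failure mode and the tests require the
wavelet detector's PPV to exceed the baseline's there.

Detector scoring uses greedy one-to-one matching at a **50 ms**
tolerance (the matching tolerance is not dictated by the method
itself; 50 ms is well under half the refractory period).

## The simulator

Templates are sums of Gaussian deflections (P, Q, R, S, T) sampled at
500 Hz: fully parametric, so the ground-truth beat index and class of
every beat are known exactly. The equine template has a −1.5 mV S
wave, a small r, and a large (0.5 mV), moderately peaked T; the human
template a +1.4 mV R and 0.3 mV T. Lead I is a 0.6-scaled projection
of lead II. Beats are placed by a jittered renewal process; APC/VPC
events are drawn as Poisson counts at the configured rates, their
preceding RR shortened to (1 − prematurity)·RR̄·U(0.85, 0.95), and a
VPC is followed by a full compensatory pause (pre+post = 2·RR̄). VPC
morphology widens the QRS by 1.6×, inverts the dominant deflection,
drops the P wave and discordantly flips the T; APC morphology is
identical to N — the class is carried by timing alone, which is
exactly what the classifier's timing pathway is for. Artefacts are
1.8 mV, ~45 Hz Gaussian-windowed bursts placed away from beats.
Noise presets: `clean` (none), `clinic` (0.15 mV wander at 0.33 Hz +
0.02 mV white), `exercise` (0.40 mV at 0.6 Hz + 0.05 mV white).

What passing tests on simulated records demonstrate: the detector's
thresholding, refractory logic and noise robustness at realistic
amplitudes and rates, and the classifier machinery end to end. What
they do not demonstrate: performance on real equine morphology
variability, electrode artefacts with spectral overlap into the QRS
band, or the printed benchmark accuracies of the full-scale datasets
— those require the original recordings and are deliberately out of
scope of the machine-checked results.

## Classifier inputs

Each detected beat yields a **2 × 500** morphology window (±0.5 s at
500 Hz, zero-padded at record edges) and a **2000-bin** binary timing
vector (±10 s at 100 Hz; a 500 Hz index *i* maps to bin ⌊i/5⌋, two
beats in one 10 ms bin keep a single 1; the center bin is always 1).
The published description uses 2 × 500/2000 in one place and
2 × 512/2048 in another; 500 and 2000 are the values consistent with
±0.5 s × 500 Hz and 20 s × 100 Hz, so they are canonical here, and
the 512/2048 variants are available by configuration as zero-padded
inputs (`.dataset_tensors` center-pads automatically).

Datasets are split 60/20/20 at random **by beat** (a record-level
split is not used by default; with per-beat splitting, beats of one
recording can appear in several splits — a known optimistic bias for
small corpora, accepted to mirror the reference protocol). Training
classes are balanced by **median resampling**: every class is
under-sampled without replacement or over-sampled with replacement to
the median class count (even class count ⇒ mean of the two middle
values, rounded). On the published human-ECG training composition
(186874/11799/37153/1878) this yields 24476 per class, 97904 beats in
total; on the equine composition (15991/1087/3699/375), 2393 per
class. Training labels come from matching reference annotations to
detections at 50 ms; unmatched detections carry `NA` and are excluded
from training.

## The parallel network

Two parallel morphology paths with independent kernel geometries read
the same 2 × W input. Convolution kernels span one lead only (size
2·`convolution_width`, stride `subsampling`, "same" zero-padding to
preserve temporal order); the two leads share weights and never mix
before flattening. Each path is
[conv → batch-norm → ReLU → dropout] × 2 plus a residual shortcut
that max-pools the path input by the product of the two strides; the
shortcut passes through a learned 1×1 convolution to match the filter
count and joins by element-wise addition before flattening (the
residual merge operation was an open choice; addition after channel
matching is standard residual practice). The timing path is two plain
1-D convolutions, each followed by dropout — no batch-norm or
residual. The flattened morphology paths share **one** dense layer
(512 units, ReLU), the timing path has its own (512), their
concatenation feeds the final dense layer (32, ReLU) and a 4-class
softmax. The ablation variant simply omits the timing branch.

Training: softmax cross-entropy + L2 (default λ = 0.001 on conv and
dense weights), dropout fraction 0.2, Adam at learning rate 1e−4,
batch size 500, 20 epochs — all configurable; the architecture search
trains with 50 epochs and early stopping at patience 3 on training
accuracy. Weight initialization is variance-scaling (He) under a
recorded seed. Because no deep-learning framework is available to R
here — and the network *is* the package's core — the engine
(convolution via gather/matrix-multiply, batch-norm, max-pool, Adam,
full backpropagation) is implemented in base R matrix code and
verified against finite-difference gradients in the tests (agreement
to ~1e−10).

Transfer learning supports two modes: `full_finetune` (source weights
as initialization, everything trainable) and `freeze_features` (only
the dense layers train; convolution, batch-norm and shortcut
parameters — and the batch-norm running statistics — are byte-for-byte
identical before and after, a contract the tests check by serializing
them). Ensembling combines models by per-beat majority vote; ties are
broken by the highest mean softmax probability among the tied labels.

## Architecture search

NSGA-II operates on a 21-gene genome in [0,1]: per conv block the
stride, kernel half-width and filter count (counts decoded on a log2
scale, matching the powers of two of the optimized architectures),
plus the dense width, L2 (log10) and dropout (linear). Default bounds
envelope the optimized values: stride [1, 32], width [5, 300],
filters [4, 64], dense [32, 1024]. Variation is simulated binary
crossover (η = 15, p = 0.9) and polynomial mutation (η = 20,
p = 1/genes); selection is binary tournament on (non-domination rank,
crowding distance) with elitist environmental selection, so the
generation-best fitness never decreases. The published procedure
names a multi-objective algorithm with a single stated objective
(validation accuracy); the implementation runs NSGA-II with accuracy
as the sole objective and offers parameter count as an optional
second objective (off by default) — the observed "network reduction"
suggests size mattered implicitly, but that is an interpretation, not
a documented setting. Identical gene vectors are cached and never
retrained within a search; un-buildable gene combinations score 0.
The GA's fitness training is a single run per individual; replicate
training (3×, averaged via `average_reports()`) is reserved for final
evaluation.

## Metrics

Per class *c* (one-vs-rest on the 4 × 4 confusion matrix): TP is the
diagonal entry, FP the rest of the column, FN the rest of the row, TN
the remainder; recall = TP/(TP+FN), PPV = TP/(TP+FP), F1 their
harmonic mean, all in percent. Overall accuracy is trace/total — the
multi-class reading of the binary accuracy formula that a single
accuracy figure implies. Aggregates are macro (unweighted) means;
classes with no true instances have undefined recall and are excluded
from the macro average. Micro-averaged recall equals overall accuracy
by construction — a property the tests verify on random matrices.
Percentages print to one decimal.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by choice:
detector quality uses ten 2-minute simulated records at 40–80 bpm
under the clinic preset (recall and PPV ≥ 95% at 50 ms required);
refractory fuzzing uses one hundred 10-second records across species,
rates and presets; classifier checks use 200-sample toy sets with a
compact configuration (window 100, timing 200) of the same
architecture, where "separable" verifies learning capacity and
"timing_only" isolates the timing pathway's contribution (APC recall
of the ablation must fall strictly below the parallel network's).
Tie-breaks: argmax ties at inference take the first class in
(N, APC, VPC, A) order; annotation collisions after resampling
deduplicate by keeping the first; resampling rescales annotation
indices by the rate ratio with half-up rounding, preserving times to
within one sample.

## Known limitations

* The simulator's artefact model (high-frequency bursts) is a
  stand-in; real artefact morphology is unconstrained and its
  published characterization is limited to "high frequency and high
  amplitude".
* The native-symbol → 4-class map for WFDB records is a documented
  default (supraventricular prematures → APC, ventricular ectopy →
  VPC, fusion/paced/unclassifiable/noise → A), shipped as a config
  file rather than hard-coded, because the exact published grouping
  is not printed.
* The WFDB reader covers single-file format 16/212 records with .atr
  annotations — enough for the MIT-BIH layout; multi-segment and
  multi-file records are out of scope.
* Training the full-scale networks to the published benchmark
  accuracies requires the original datasets and is outside the test
  suite by design.
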