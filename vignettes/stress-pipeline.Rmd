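---
title: "Stress classification from wearable biosignals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress classification from wearable biosignals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(stresswear)
```

## The problem

stresswear implements a complete analysis pipeline for three-class stress
detection from wearable physiological recordings: 3-channel
photoplethysmography (PPG, green/red/infrared, 55 Hz), single-lead ECG
(512 Hz) and single-channel EEG (512 Hz), collected while participants
solve cognitively demanding puzzles under different environmental
conditions. Each 15-minute session carries one self-reported stress score
on a 0–8 scale, mapped to three classes: 0–4 = relaxed, 5–7 = medium
stress, 8 = high stress.

The emulated study design has 30 participants, half solving
medium-difficulty and half hard puzzles, each recorded in three scenarios
(1: noisy/disturbing stimulation, 2: observed by another person,
3: comforting stimulation). Because recordings of this kind are typically
not redistributable, the package ships a synthetic cohort generator that
reproduces the statistical structure the classifiers rely on, so the whole
pipeline is testable end to end without any external data. Real recordings
in the same plain-text session format are consumed by the identical code
path (`read_session_dir()`).

## The synthetic cohort generator

The generator is deliberately a set of *simple parametric* waveform models
whose only purpose is to carry class-dependent physiology:

* **ECG** — beats from a stochastic RR-interval process with mean
  `60/hr` s and Gaussian jitter; each beat stamps a PQRST template built
  from five Gaussian deflections. Baseline wander and white noise are
  added. Mean heart rate increases with the stress class (default
  62/74/86 bpm plus a stable per-participant offset) and RR jitter
  (heart-rate variability) decreases (0.05/0.035/0.02 s) — the two
  classical cardiac stress signatures.
* **PPG** — one two-Gaussian pulse (systolic peak + dicrotic hump) per
  ECG beat, delayed by a fixed pulse-transit offset; the three optical
  channels are amplitude-scaled copies with independent sensor noise, so
  they are near-perfectly correlated in the noise-free limit.
* **EEG** — a 1/f-coloured background plus amplitude-modulated alpha
  (10 Hz) and beta (20 Hz) oscillations; the alpha/beta band-power ratio
  decreases with stress (1.6/1.1/0.7).

Self-report scores come in two modes. `"skewed"` is calibrated so that
the pooled class mix approaches 74.4 % / 21.1 % / 4.4 % (the emulated
study's segment counts: 6030/1710/360 over 8100 segments), expected stress falls
from scenario 1 to scenario 3, and the hard-puzzle group is more stressed
than the medium group under the noisy scenario 1. The per-scenario class
probability tables behind this are invented calibrations — the study
reports only aggregate counts — and are documented in
`stresswear:::class_prob_table`. `"balanced"` draws the three classes
uniformly and exists for clean model-recovery experiments.

What the generator does **not** emulate: device-specific artifacts,
motion-artifact bursts, electrode pops, inter-channel timing offsets, or
any true physiological coupling between EEG and cardiac state. A model
that recovers classes from this generator has demonstrated that the
architecture and training loop can extract class-dependent spectral and
morphological structure — not that it would reach comparable accuracy on
human data.

```{r cohort}
spec <- cohort_spec(n_participants = 4, n_medium = 2, n_hard = 2,
                    session_minutes = 1)
coh <- generate_cohort(spec, seed = 1, modalities = "ecg")
coh$manifest[1:4, 1:6]
```

## Preprocessing

The chain is: fixed-grid resampling → Butterworth band-pass → 10 s
segmentation → per-segment normalization, in that order.

* **Resampling** maps every channel onto a fixed 230,400-sample grid
  (15 min × 256 Hz) regardless of native rate *and actual duration*. A
  session that ended early is time-normalized onto the full grid rather
  than zero-padded; this is the only reading under which every session
  yields the same count of 230,400 points, and it makes the segment count
  (90 per session, 8100 per 90-session cohort) an invariant rather than a
  coincidence. Implementation: an order-8 zero-phase Butterworth low-pass
  at 90 % of the target Nyquist when decimating (anti-aliasing), then a
  natural cubic spline onto the target grid. Zero-phase filtering uses
  odd-reflection edge padding so constants map to constants exactly and
  record edges carry no startup transients.
* **Band-pass**: PPG 0.5–5 Hz, ECG 5–15 Hz, EEG 0.1–15 Hz, each an
  order-4 Butterworth applied forward–backward (zero phase, magnitude
  squared). The order and the zero-phase choice are the package's own —
  order 4 is the standard biosignal compromise between roll-off and
  passband flatness, and zero-phase application preserves waveform
  morphology. `butter_gain()` exposes the closed-form magnitude response
  the test-suite checks the implementation against.
* **Segmentation**: non-overlapping 10 s windows of 2,560 samples;
  230,400/2,560 = 90 exactly, trailing remainders of shorter inputs are
  dropped (floor semantics).
* **Normalization**: per-segment, per-channel z-score (normalization
  happens after segmentation, so statistics are local to the window);
  constant channels are zero-filled behind a warning.
* **Labels** are per-session (one questionnaire per trial) and broadcast
  to the session's 90 segments.

## Self-supervised pretext task

Five transformations of normalized segments — additive Gaussian noise
(σ = 0.01), amplitude scaling (×1.1), negation, time reversal, and piece
permutation (20 random non-overlapping pieces of 64 samples = rate/4,
rearranged) — define a 6-way recognition task (label 0 = untransformed).
Time warping is deliberately not included. Design choices made here:

* The task is posed as a single 6-way classification rather than
  per-transformation binary heads; both readings are defensible, and the
  6-way head is the simpler model of "recognize which variant you see".
* "Swapping" the permuted pieces is implemented as a derangement (no
  piece keeps its position), which maximizes the learnable signal; a
  plain random permutation is available via `transform_spec(derange =
  FALSE)`.
* Piece positions are drawn uniformly over all non-overlapping
  placements by a stars-and-bars construction (20 pieces of 64 samples
  occupy half the segment, so naive rejection sampling is infeasible).

## The three architectures

All models consume `[channels × 2560]` segments and emit 3 logits; they
are implemented on an in-package reverse-mode engine (im2col convolutions
over BLAS, exact layer-wise gradients, Adam) — see `R/nn-engine.R`.

**StressNeXt** — a 1×1 convolutional projection (to width 64), then four
multi-kernel blocks: parallel convolutions with kernels 1/3/5/7 whose
outputs are combined *by elementwise addition* (not concatenation),
followed by batch normalization, ReLU and stride-2 temporal
downsampling; global average pooling and a dense head close the model.
The branch width, the normalization placement and the downsampling
factor are package choices; the multi-kernel family fixes the topology,
not the widths.

**LRCN** — two width-64 convolutions (kernel 7) with ReLU, max pooling,
two width-64 residual blocks (two kernel-3 convolutions plus identity
skip) separated by max pooling, then two stacked LSTM layers (hidden
128) whose final state feeds the dense head. This is the 1-D baseline of
the attention-LRCN family: no attention module, no STFT input.

**Self-supervised CNN** — a shared encoder of three blocks (two
convolutions + max pool of size 8, stride 2 per block; 32 filters of
size 32, 64 of 16, 128 of 8), global max pooling to a 128-feature
embedding, and two dense heads: 6-way pretext and 3-way classifier. The
heads share the encoder *by reference*, so pretraining updates are
visible to the classifier with no copying. Convolutions are unpadded in
blocks 1–2 and same-padded in block 3: under that arithmetic the
feature maps are 128 × 605 after block 2 and 128 × 299 after block 3.
No single standard padding convention yields a 605-step map *after*
block 3, so the implementation asserts its own computed shapes (exposed
as `attr(encoder, "shapes")`) rather than hard-coding any particular
intermediate. After pretraining, the encoder is fine-tuned during
classification by default; `freeze_encoder = TRUE` trains the head only.

```{r shapes}
enc <- build_sscnn_encoder(model_spec("sscnn", in_channels = 1), seed = 1)
attr(enc, "shapes")
```

## Training and evaluation protocol

Stratified 3-fold cross-validation at segment level; Adam with learning
rate 0.001; cross-entropy loss; 300 epochs for classifiers and 150 for
pretraining as protocol defaults (desk-scale runs use far fewer — see
below); batch size 64 by default. Two protocol details deserve note:

* **Fold metric**: the default `"epoch_mean"` mode scores a fold as the
  *mean of the per-epoch validation metrics*, which is the stated
  protocol rule even though final-epoch evaluation is more conventional;
  `"final_epoch"` mode is provided.
* **F1 averaging is macro.** Under the skewed imbalance
  (6030/1710/360) a near-constant majority-class predictor scores 74.4 %
  accuracy but only ≈ 28.4 % macro-F1 — exactly the signature of a
  degenerate classifier that weighted averaging would hide. The metric
  suite treats zero-denominator per-class ratios as 0.
* **Leakage caveat**: stratifying 8100 segments ignores that segments of
  one session share a participant, so fold metrics estimate
  within-cohort interpolation, not subject-level generalization.
  `evaluate_suite()` evaluates the protocol as specified; a grouped
  (per-participant) split would be the honest generalization estimate
  and is a natural extension.

`evaluate_suite()` crosses models with the seven signal combinations
(PPG, ECG, EEG, and their unions; PPG contributes 3 channels, ECG and EEG
one each), and computes scenario and difficulty breakdowns — by default
retraining on each subset (each breakdown cell is an independent
experiment), with a `"slice"` mode that instead slices the global
validation predictions.

## Desk-scale problem sizes

The package's own test-suite and reproduction script run everything on
one CPU; the sizes are chosen accordingly and stated here as the
package's reference configuration:

* structural checks (grid length, segment counts, 8100-segment cohort)
  run at full size — they are cheap;
* model-recovery experiments use a balanced 6-participant × 3-scenario
  ECG cohort with exaggerated class separation (60/90/120 bpm),
  subsampled to 120 segments, ≤ 30 epochs, batch 16, with early
  stopping once validation accuracy is clearly established. Under these
  conditions all three architectures exceed 80 % validation accuracy
  within a dozen epochs, and the 6-way pretext task exceeds 60 %
  (chance 16.7 %);
* the pretext stage builds six examples per source segment, so it runs
  on a training subset (24 source segments → 144 pretext examples) to
  stay proportionate.

Numerical conventions: argmax ties break to the lowest class index;
weight initialization is fan-in-scaled Gaussian (uniform for LSTM) under
a recorded seed; all randomness flows from user-supplied seeds through
deterministic per-stage child seeds, so every run is exactly
reproducible.

## Known limitations

* The synthetic generator's class signal is stronger and cleaner than
  human data; accuracies reported on human cohorts are neither expected
  nor reproduced by this package.
* The engine is CPU-only and optimized for clarity at desk scale, not
  for large-scale training.
* Only the five stated transformations are implemented; time warping is
  intentionally out of scope, as is the attention module of the LRCN
  family and 2-D (STFT) inputs.
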