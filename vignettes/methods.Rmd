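---
title: "Temporal localization of swallowing phases: models, generator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal localization of swallowing phases: models, generator, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the event
calculus, the synthetic data model, the three network variants and their
training, the numerical choices behind them, and what the shipped tests do
and do not establish about real clinical data.

## 1. The event calculus

A videofluoroscopic swallowing study (VFSS) clip is analyzed from the first
frame of the first sub-swallow, so `oral_start` is frame 0 by construction.
Seven events are labeled per clip; seven temporal parameters are differences
of event frame indices converted to milliseconds at the recording rate
(15 FPS, one frame = 66.67 ms).

Two parameters are signed: the hyoid burst can precede the bolus passing the
mandible (negative pharyngeal delay time), and vestibule closure can precede
the hyoid burst (negative LVC reaction time). Both orders occur clinically,
so the calculus neither rejects nor clamps them. Consequences adopted
throughout:

- **Half-open intervals.** A phase occupies `[start_event, end_event)`:
  events mark "the first frame in which" something is true, which maps to
  inclusive starts and exclusive ends, and adjacent phases then partition
  frames without double counting.
- **Reversed intervals.** When the end event precedes the start event (PDT,
  LVCRT), the interval is represented as `[min, max)` with a `reversed`
  flag, and the parameter keeps its sign. The frame-level identity
  `PTT = PDT + PRT` is exact in integer frame counts; in milliseconds it
  holds to floating-point rounding of the 1000/15 factor.
- **No constraint between LVC offset and UES closure** — none is warranted.
- **Rounding.** Durations are kept at full precision internally; seconds are
  rounded half-to-even to three decimals only for presentation, matching the
  convention of published phase-duration tables. One published table row
  (LVC duration: 10.053 frames but 0.676 s) is internally inconsistent at
  15 FPS (10.053/15 = 0.670); the frame column is treated as primary and the
  package does not force agreement.

## 2. The synthetic clip generator

No public VFSS corpus exists, so models and metrics are exercised on a
schematic lateral-view scene: a mandible line and pharyngeal wall, a bright
bolus disc, a hyoid marker, a vestibule rectangle whose dark air space
disappears during closure, and a UES gate bar that opens and closes. The
renderer is written so that every event is recoverable from pixels by
independent read-back oracles (bolus leading-edge column, vestibule mean
intensity, gate state, hyoid centroid); a generator/annotation consistency
test requires recovery of every event to within one frame. The bolus
leading edge crosses the mandible line exactly at `bolus_past_mandible`
(pre-crossing positions are clamped a pixel left of the line so rounding
can never cross early), and its pharyngeal path descends just behind the
mandible line and travels below the vestibule rectangle, keeping the
oracles' regions unpolluted.

**Durations.** The published per-phase statistics give only mean ± SD of
frame counts (OPD 27.658 ± 34.215, PDT 20.809 ± 42.856, PRT 10.148 ± 2.060,
LVCRT 4.526 ± 1.687, LVCD 10.053 ± 3.987, UESOD 6.483 ± 1.746). Frame
counts are integers of at least 1, so draws are rounded normals floored at
one frame. For phases whose SD exceeds the mean, naive truncation would
inflate the mean by many frames, so the latent normal's location is solved
(by `uniroot` on the exact discretized expectation) to make the expected
drawn frame count equal the published mean — the first moment is matched
exactly, the SD approximately. PTT is not sampled; it is PDT + PRT per
clip. (The published PTT row, 29.676 frames, is slightly below the sum of
the PDT and PRT rows — per-clip identities do not constrain column means in
a table of independent row summaries — so the generator's PTT mean is the
sum, 30.957.)

**Reversed events.** The published account notes reversed PDT/LVCRT but not
their frequency; the generator flips PDT with probability 0.1 and LVCRT
with probability 0.05 by default, by a small offset (1–3 frames for PDT,
1–2 for LVCRT, clinically plausible magnitudes), bounded so all event
indices stay valid. The calibration test disables the flips to check the
sampled means against their targets; a separate test checks the realized
flip rate.

**Irregularities** mimic what real recordings contain: gradual drift of the
scene toward the frame edge, a static occluding rectangle over the throat,
a hand-like blob sweeping through, per-frame contrast jitter, and additive
Gaussian pixel noise (SD 0.01 by default), all clamped to [0, 1].

**What the generator does not emulate:** photorealistic fluoroscopy,
anatomically accurate kinematics, inter-phase correlation (phases are
sampled independently — whether a long oral phase predicts a long delay is
unknown from summary statistics alone), multiple sub-swallows, or residue
from prior boluses. Passing the shipped end-to-end tests therefore shows
the architecture, training loop and duration calculus work as specified on
separable video; it does not certify clinical performance, which in the
source setting additionally relied on large-scale video pretraining.

## 3. Networks

The backbone is ResNet3D-18: a 3×7×7 stem convolution with spatial stride
2, then four stages of two residual blocks (each 3×3×3 conv → batch norm →
ReLU → 3×3×3 conv → batch norm, plus skip, then ReLU; 1×1×1 convolution
with batch norm on skips that change shape). Stage widths default to
[64, 128, 256, 512] and scale down (e.g. [4, 8, 16, 32]) for CPU-scale
work; the "18" counts the stem, the sixteen block convolutions and the
final fully connected layer.

- **DEFAULT**: global average pooling over time and space, one FC layer,
  two-class softmax. The two-class softmax head (rather than a single-logit
  sigmoid) follows the source architecture's class-probability head.
- **BIDIRECTIONAL**: two *separate* backbones (no weight sharing) for the
  forward and backward L-frame streams. "Combined and concatenated" is
  implemented as concatenation of the two pooled penultimate feature
  vectors — concatenating two softmax outputs would hand the final FC a
  nearly degenerate 4-vector — followed by a single FC + softmax. Both
  backbones are initialized identically from the seed and trained jointly.
- **CONV-SA**: temporal strides fixed to 1 *in time only* — the motivation
  is equal input/output temporal length, which constrains nothing spatial,
  so spatial strides keep the standard schedule and spatial-only global
  pooling yields one feature per frame. Sinusoidal (Transformer-standard)
  positional encoding is *added* to the frame features, then one multi-head
  attention layer (4 heads by default; the head count must divide the final
  stage width) and a shared per-frame FC + softmax. One attention layer is
  used ("a multihead attention layer", singular), no residual connection or
  layer norm around it.

Training from scratch uses He initialization; video pretraining is out of
scope here (the hooks to load external weights via checkpoints exist, but
no test depends on them).

The engine itself — conv3d forward/backward as C++ im2col + BLAS gemm,
batch norm, pooling, attention and the heads in base R with hand-written
backpropagation — is part of the package and is verified by
finite-difference gradient checks through entire networks of all three
variants.

## 4. Windowing

- Window length L must be odd so "the center frame" is unambiguous (7 and
  13 are the studied values).
- The default edge policy is `replicate` (edge frames repeated), so every
  frame of every clip receives a prediction — required to reconstruct
  full-length intervals; `drop` (interior centers only, `T − L + 1`
  windows) is available. The source setting's boundary handling is
  unstated; replicate is the choice here.
- CONV-SA segments tile the clip with stride = W (non-overlapping; the
  source stride is unstated), the final partial segment padded by frame
  replication and masked out of the loss and of reconstructed tracks.
- Windows are index views; frames are gathered (and spatially average-pooled
  to the model's input size, once per clip) only when a batch is built.

## 5. Training and evaluation

Hyperparameters are unstated in the source account, so the package makes
them explicit config with these defaults: Adam (lr 1e-3), class-weighted
cross-entropy with weights `N/(2 N_c)` (frame-level phase detection is
heavily imbalanced — only a small fraction of frames belongs to the
phase), batch 16, decision threshold 0.5, model selection by best pooled
validation F1 (a validation split exists in the source protocol but no
criterion is stated). AP is computed threshold-free from the raw scores,
non-interpolated, ties broken by stable original order. Undefined
precision/recall/F1 (zero denominators) are reported as `NA` with an
`undefined` flag, never silently 0 or 1.

Metrics are pooled over all test frames into one confusion table (the
frame-count metric definitions suggest pooling); per-clip averaging is
available as a switch. Repeat aggregation (`repeat_experiment`, default 20
repeats in the config, fewer in desk-scale runs) reports mean and *sample*
SD (n−1), rounded to three decimals for presentation only.

Prediction tracks become intervals by thresholding plus either the bounding
span (`none`), the longest contiguous run (`longest_run`, the default
bridge to durations), or gap-closing followed by longest run
(`close_gaps(k)`). An all-negative track is the legal empty interval
`[0, 0)`, flagged rather than fabricated.

## 6. Problem sizes and reproducibility

Desk-scale defaults are chosen so the whole suite runs on one CPU: 64×64
rendered clips pooled to 32×32 (or 16×16 for smoke runs) model input,
stage widths [4, 8, 16, 32] (tests also use [2, 4, 8, 16]), 120-clip
datasets for the end-to-end check and 30-clip smoke pipelines, three
training epochs with at most 40 windows per clip per epoch — the easy
fixture saturates validation F1 within one epoch, so more would be waste.
The full-size configuration (224×224, widths [64, 128, 256, 512], 20
repeats) is reachable through the same config objects.

All randomness flows from one root seed through named sub-seeds (data /
init / per-epoch shuffling / per-repeat), `.Random.seed` is saved and
restored around every seeded operation, and reruns of the pipeline with the
same root seed write byte-identical annotation and metric CSVs (verified by
test). Checkpoints store weights plus the full model config and refuse to
load into a mismatched architecture.

## 7. Known limitations

- Synthetic-only evidence: see §2. The irregularity models are stylized.
- One binary model per phase (consistent with the per-phase repeat
  protocol); a shared multi-label model is future work.
- Batch-norm statistics make training batch-order sensitive; determinism is
  guaranteed per seed, not across different batch sizes.
- The duration bridge reports the longest run only; swallows with genuinely
  fragmented phase predictions lose the fragments (gap-closing mitigates).
- AP is undefined for test sets with no positive frame for a phase and is
  reported as an error, not imputed.
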