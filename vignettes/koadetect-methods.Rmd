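---
title: "Methods: anchor-free graded lesion detection for knee radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchor-free graded lesion detection for knee radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koadetect)
```

## The problem

Knee osteoarthritis (KOA) is graded on radiographs with the
Kellgren–Lawrence (KL) scale, K0 (normal) through K4 (severe), based on two
radiographic signs: narrowing of the joint space between femur and tibia
and the formation of osteophytes (bone spurs) at the joint margins. The
clinical task is simultaneously a *localization* problem (where is the
joint lesion?) and an *ordinal classification* problem (how severe?).
`koadetect` frames this as single-stage, anchor-free object detection: each
location on a multi-scale feature pyramid predicts five class scores and a
box expressed as four boundary distances, and the highest-scoring boxes
after non-maximum suppression (NMS) are the detected lesions with their
grades.

## Model

**Backbone.** A compound-scaled, MBConv-based convolutional feature
extractor. From a base stage table (seven MBConv stage groups between a
stride-2 stem and a 1×1-conv/pool/FC head), a width multiplier scales
channel counts (rounded to multiples of 8, never below 90% of the scaled
value) and a depth multiplier scales per-stage repeats (ceiling). The
default profile uses width 1.4 and depth 1.8 — the published stage table we
target contains rounding artifacts (e.g. 45/22/34 channels where the
scaling rule gives 48/24/32), so the implementation derives the profile
from the scaling rule rather than hard-coding printed values, and records
the resulting channels in `summary()`. Each MBConv block is: 1×1 expansion
(normalization + swish), depthwise k×k convolution, squeeze-and-excitation
channel gating, 1×1 linear projection, and a residual connection when the
stride is 1 and channel counts match. The detector taps the stride-8, -16
and -32 stage-group outputs (C4, C5, C6).

**Neck (PAFPN).** The three taps are projected to a uniform width by 1×1
laterals, fused coarse-to-fine (nearest-neighbour 2× upsampling, addition),
then aggregated fine-to-coarse with 3×3 stride-2 convolutions and ReLU;
two further stride-2 convolutions off P5 give P6 and P7, for five levels at
strides 8–128. Where the narrative calls for adaptive fusion weights
without giving a formula, every two-map addition carries two learnable
logits through a softmax scaled by 2, so the zero-init reproduces the plain
sum exactly and the plain-sum variant remains a config flag. Disabling the
bottom-up stage reduces the neck to a plain FPN (the ablation baseline).

**Task-aligned head.** Six 3×3 convolutions (32-group normalization, ReLU)
compute task-interaction features shared by both tasks. Per task, layer
attention pools the concatenated stack, passes it through two FC layers and
a sigmoid, and rescales each of the six layers by its weight ω_k ∈ (0,1)
before a 1×1 reduction and the prediction convolution. Classification
passes through a sigmoid; localization emits four raw values mapped to
positive distances by `stride × exp(s_l · z)` with a learnable per-level
scale `s_l` (head weights are shared across levels). Two alignment maps are
learned from the interaction stack through two stacked 1×1 convolutions
each: a spatial probability map `M ∈ (0,1)^{H×W}` that refines the scores
as the geometric mean `P^align = sqrt(P·M)` (a plain product is a config
switch), and an 8-channel offset map `O` holding one (Δi, Δj) pair per box
boundary; each boundary distance is re-sampled at its offset position by
bilinear interpolation, so every boundary can borrow the most accurate
nearby prediction. The offset convolution is zero-initialized, making
alignment start as the identity. Setting `task_aligned = FALSE` gives the
plain decoupled head used in the ablation.

**Losses.** Box regression uses the EIoU loss
`L = (1 − IoU) + ρ²(b, b^gt)/c² + (w − w^gt)²/c_w² + (h − h^gt)²/c_h²`,
where ρ is the center distance, c² the squared diagonal of the smallest
enclosing box and c_w, c_h its width and height: penalizing the edge
lengths directly avoids the CIoU pathology in which the width and height
gradients of the aspect term always carry opposite signs
(`ciou_aspect_gradients()` exposes this diagnostic, and GIoU/DIoU/CIoU are
provided as reference objectives only). Classification uses a focal loss
`−s·(1 − p_t)^γ·log p_t` with γ = 2, where the difficulty scale factor is
realized as `s = (1 − p)^α` for positives and `s = p^α` for negatives
(α = 0.5, configurable) — the published form of the scale factor is not
printed, so this monotone "harder weighs more" realization is a documented
choice. The total objective is `1·cls + 1·reg` (both weights exposed); the
sum is normalized by the number of positive anchors (floor 1). A
pixel-level weighted binary cross-entropy is provided as an optional
auxiliary objective and is off by default, since its role relative to the
main objective is ambiguous in the source material.

**Assignment (TAL).** Anchors inside a ground-truth box are ranked by
`m = score^a · IoU^b` with a = 1, b = 6, and the top k = 13 become
positives (an anchor claimed twice goes to the higher m; a box with no
interior anchor falls back to its closest anchor). These are the published
task-aligned-learning defaults, adopted because the source names the
mechanism without printing the formula; all three are config fields.

**Optimization.** AdamW at learning rate 2e-4, weight decay 1e-4 with
normalization parameters exempt, batch size 1, linear warmup over 500
iterations from ratio 0.001, step decay ×0.1 at epochs 8 and 11, 50 epochs.
These full-scale defaults are kept verbatim in `train_config()`.

## Numerical choices

* **Differentiation.** The network is trained by a small reverse-mode tape
  built into the package (dense and depthwise convolutions via
  im2col/col2im C++ kernels, group/batch normalization, bilinear offset
  sampling with gradients to both operands). Loss gradients with respect to
  the head outputs are closed-form for the focal term and central finite
  differences (step 1e-3) for the box term; the finite difference is exact
  to O(h²) and robust at the min/max kinks of the enclosing-box terms.
  Every operation's backward pass is validated against finite differences
  in the test suite.
* **Normalization at batch size 1.** With one image per step the batch
  statistics of batch normalization degenerate to per-image spatial
  statistics; the implementation uses those consistently in training *and*
  evaluation (instance-style normalization), because normalizing with
  running averages at eval while training normalized per image creates a
  distribution mismatch. Running estimates are still tracked.
* **Probabilities** are clamped to [1e-7, 1 − 1e-7] rather than raising on
  boundary values.
* **Boxes** are continuous, widths are `x_max − x_min` with no "+1" pixel
  convention, and zero-area boxes are legal values contributing 0 to IoU.
* **NMS** defaults: IoU threshold 0.6, score floor 0.05, at most 100
  detections per image, top-100 decoded candidates per level — the source
  names NMS but no thresholds, so these common one-stage-detector values
  are config fields. Ties in score break by lower index for determinism.
* **Evaluation.** A detection is correct iff the class matches and IoU is
  *strictly* greater than the threshold. AP integrates the monotone
  (right-max) envelope of the PR curve over all points; 11-point
  interpolation is available for comparability. mAP is reported at IoU 0.5
  and 0.75 since the headline threshold is not stated. The confusion matrix
  attributes each ground truth to its best class-agnostic detection at
  IoU ≥ 0.5, with a "missed" column.
* **VOC XML** stores 1-based inclusive pixel indices; minima are shifted by
  one on read/write so integer fixtures round-trip exactly. The annotation
  CSV dialect is `filename,x_min,y_min,x_max,y_max,label` with required
  header.
* **Splitting** is per-class with floor rounding (`floor(0.8·n)` to train),
  the only rule that reproduces the published per-grade 8:2 composition
  exactly.

## The synthetic phantom generator

The pipeline is exercised end to end on seeded synthetic radiograph
phantoms rather than the external clinical dataset. Each phantom renders
two soft-edged bone bodies separated by a joint gap drawn from a per-grade
range that narrows from K0 to K4, adds semicircular osteophyte bumps at
the joint margins whose count grows with grade, then applies Gaussian blur
and additive noise; the single ground-truth box encloses the joint region.
Grade is thus encoded by *two* monotone cues, so classification cannot
collapse onto a single linear feature and localization is genuinely
exercised. The default canvas is 162 × 300 (the native resolution of the
radiographs the pipeline targets); the per-grade gap ranges
(34–40, 26–32, 18–24, 10–16, 3–8 px) are disjoint by construction, and a
deliberately trivial gap-threshold classifier must reach ≥ 90% accuracy on
default phantoms — certifying that the detection task is learnable at desk
scale. All randomness derives from a single config seed.

What the phantoms deliberately do **not** emulate: real anatomical shape
variation, subchondral sclerosis and cysts, exposure and positioning
variability, and the ordinal ambiguity between adjacent KL grades that
makes clinical K1/K2 hard. Passing the end-to-end tests therefore
demonstrates that the architecture, losses, assignment and optimization
interoperate and can fit a learnable graded-detection task on CPU — not
that clinical-grade accuracy would be reached on real radiographs.

## Problem sizes used by the tests

The tiny profile (backbone width 0.25, depth 0.4; 32-channel pyramid;
64 × 64 phantoms) runs the identical code path as the full profile. The
end-to-end check trains on 60 phantoms (12 per grade) with 15 held out,
for 15 epochs at batch 1 (900 optimizer steps) with learning rate 1e-3,
warmup 50 iterations and decay at epochs 12 and 14 — the same
warmup/two-step-decay shape as the full recipe, compressed. It requires a
median mAP@0.5 of at least 0.6 over three seeds and that the full
configuration (PAFPN + task-aligned head + EIoU) not fall below the
plain-FPN/plain-head/L1 baseline under identical seeds — the desk-scale
analogue of the published ablation ordering. The gradient-descent
convergence property compares EIoU and GIoU objectives from identical
anchors (step 0.05, 20 cases per seed, 3 seeds, convergence at IoU ≥ 0.99).

## Known limitations

* Training is CPU-bound and single-image; the engine is built for
  correctness and testability at desk scale, not throughput.
* ImageNet-style pretraining is out of scope; an optional checkpoint hook
  loads externally supplied weights but none ship with the package.
* FPS numbers from `evaluate_detector()` measure this R implementation and
  are reported for completeness, never asserted in tests.
* The offset-map gradient is one-sided exactly on integer offsets (a
  bilinear-interpolation knot); training moves offsets off the knots
  immediately, and the backward pass is exact elsewhere.
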