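---
title: "Semi-self-supervised wheat head segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-self-supervised wheat head segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pixel-level annotation of field images is the bottleneck for semantic
segmentation of dense, self-similar plant organs. Wheat heads (spikes) are a
canonical case: a single frame can hold dozens of mutually occluding heads,
and masking them by hand takes hours per image. `wheatseg` implements a
pipeline that builds a competent binary head-vs-background segmenter from as
little as **one or two manually annotated video frames**, a short unannotated
clip of the same field, and a few clips of head-free background scenes.

The pipeline has four ingredients:

1. **Cut-and-paste synthesis.** Real head cutouts are extracted from the
   annotated frame; "fake" cutouts — background texture cut with the exact
   footprints of real heads (cookie cutters) — are extracted from head-free
   regions of the same frame. Composites are assembled on background frames:
   fake heads first, then real heads, each geometrically augmented, with the
   union of the placed real footprints forming an exact, computationally
   derived mask. The fakes are negative examples in head shape: without
   them a model can learn to fire on paste-boundary contrast artifacts
   rather than head texture.
2. **An encoder–decoder segmentation network** trained with the combined
   binary cross-entropy + Dice loss.
3. **Three domain-adaptation stages** that progressively bridge the gap
   between composites and real frames: full-circle rotations of the
   annotated frames (model D), pseudo-labeling of the unlabeled clip frames
   (model P), and few-shot fine-tuning on a handful of annotated images
   (model G). A conventional supervised Baseline trains on the few-shot set
   alone for comparison.
4. **Majority-vote test-time augmentation** over the original image and two
   photometric variants (Gaussian noise, sepia), plus Dice/IoU evaluation
   with per-domain reporting.

## Data partitioning

`partition_frames()` splits a clip's frames into five parts: the synthesis
frames `w_t` and `w_v`, a held-out test set, a validation set, and the
unlabeled pool used for pseudo-labeling. Test and validation frames are
sampled uniformly (seeded) from frames lying **strictly more than one
second** — `round(fps)` frame indices — from both `w_t` and `w_v`. Video
frames seconds apart are still correlated, but frames *within* a second are
near-duplicates; the exclusion window prevents the most direct leakage from
the synthesis frames into the evaluation sets. We apply the same window to
the validation set; the weaker alternative (window on the test set only)
would let near-duplicates of `w_t` steer model selection. `w_t` and `w_v`
are excluded from every other part.

## Image synthesis

`compose()` draws the number of fake and the number of real heads
independently and uniformly from 10–100 (the package default), samples
cutouts **with replacement**, augments each one, and pastes it at a uniform
random position. Design choices worth knowing:

- **Painter's order.** All fakes are placed below all reals, so the ground
  truth mask is exactly the union of the clipped real footprints: a real
  head occluded by a later real head loses those pixels from its own
  contribution, but the occluding head re-adds them. Every sample carries a
  placement log (cutout id, center, transform, transformed footprint) from
  which the mask can be re-rasterized independently; tests assert exact
  equality.
- **Border clipping.** Placements extending past the canvas are clipped,
  not rejected — real field images truncate heads at frame borders.
- **Geometric augmentation** (`aug_params()`): horizontal/vertical flips
  (p = 0.5 each), rotation in [−180°, 180°], isotropic resize in
  [0.5, 1.5], and a small elastic deformation (peak displacement 2 px,
  field smoothing σ = 4, p = 0.3). The identical sampled map is applied to
  patch and footprint; footprints are re-binarized at 0.5 after
  interpolation and the transform is resampled if it empties a footprint.
  The named transform families are fixed; the ranges are package defaults
  chosen to keep augmented heads recognizable at the 5–15 px scale of the
  fixture heads.
- **Color augmentation** applies brightness/contrast jitter, per-channel
  gain, occasional blur and Gaussian noise to the composite image only —
  never to the mask (asserted by test).

`synthesize_dataset()` derives the seed of image *i* as `base_seed + i − 1`,
making every dataset byte-reproducible. The reference protocol uses 10,000
training and 1,000 validation composites; the fixture-scale runs in this
package use 60–300 (see *Problem sizes* below).

## Model and loss

`build_model()` constructs a U-Net-style encoder–decoder: per level two 3×3
convolutions with ReLU and 2×2 max pooling, a double-width bottleneck, and a
mirrored decoder with nearest-neighbour upsampling and skip concatenations,
closed by a 1×1 convolution that emits one logit per pixel. Probabilities
are sigmoids of the logits. The architecture is configurable by design —
the method, not a specific backbone, is what the package implements. The
`"tiny"` preset (widths 6, 12; ≈17k parameters) trains in CPU-minutes and is
used throughout the tests; `"base"` (16, 32, 64) is the larger default for
real images. Pretrained encoder weights are not bundled, so initialization
is always seeded He-scaled Gaussian noise; `pretrained_init = TRUE` raises
an error rather than silently downloading anything.

The loss (`combined_loss()`) per image is

    L = [1 − (2 Σ p·g + ε) / (Σ p + Σ g + ε)] − (1/N) Σ [g log p + (1−g) log(1−p)]

averaged over the batch, with ε = 1e−5 smoothing the Dice term against
empty masks and probabilities clamped to [1e−7, 1 − 1e−7] inside the
logarithms (the loss is undefined at p ∈ {0, 1}). Gradients are
hand-derived and verified against finite differences to 1e−3 relative
error; the loss itself is verified against an independent per-pixel scalar
oracle to 1e−6.

Training (`train_stage()`) uses SGD with learning rate 0.01 (the protocol
value) and momentum 0.9 — the loss landscape of even the tiny network is
rough enough that plain SGD at this rate crawls; momentum is the standard
companion and is exposed as a config knob. The checkpoint returned is the
epoch with the **minimum validation loss**, never the last epoch. Epoch
counts per stage are not part of the protocol and default to 10 at fixture
scale.

## Domain adaptation

- **Stage D** trains on all 360 integer-degree rotations (0°–359°, the
  original being 0°) of `w_t`, validated on the rotations of `w_v`. The
  canvas expands to contain the rotated frame (zero fill) rather than
  cropping, so no head pixels are lost; 0/90/180/270° are computed exactly
  by array transposition because resampling at those angles is avoidably
  lossy. Records are flagged for *online* strong augmentation: flips
  applied jointly to image and mask (label-preserving), photometric jitter
  to the image only, resampled at every access.
- **Stage P** predicts masks for the unlabeled pool with model D
  (threshold 0.5, hard labels, no confidence weighting — the protocol
  states prediction then fine-tuning, nothing more) and fine-tunes on them.
  The validation frames are unannotated too, so they are pseudo-labeled
  with the same model; this is the only reading that yields a validation
  loss without extra annotation.
- **Stage G** expands the few-shot annotated sets with the same rotation
  machinery and fine-tunes model P. The **Baseline** trains from scratch on
  exactly the stage-G data.

Online strong augmentation is applied only where records are flagged
(stage D by default); whether stages P and G should also use it is left as
a flag (`online_augment`, default off for their datasets).

## Metrics and TTA

`dice_score()` and `iou_score()` implement 2|O∩E|/(|O|+|E|) and
|O∩E|/|O∪E|; both return 1 when both masks are empty (the 0/0 case reads as
perfect agreement, and the convention is testable). `evaluate()`
macro-averages per-image scores overall and per domain; pooled pixel
counting is the alternative reading, but macro-averaging weights every
image equally and matches per-domain reporting. `tta_predict()` votes over
the original, a Gaussian-noise variant (σ = 0.05 on the [0,1] scale) and
the fixed-matrix sepia variant; both variants are photometric, so the three
binarized predictions align pixel-wise and three voters cannot tie.
`binarize()` uses the ≥ threshold convention.

## The field simulator

`fieldsim` generates the package's test bed: seeded, hence exactly
reproducible, and with masks that are correct **by construction** — zero
annotation noise. Backgrounds are low-frequency color blotches plus pixel
noise in a soil/vegetation palette. Field frames add stem strokes (absent
from background clips — a genuine appearance difference between the two
domains) and textured-ellipse heads with stripe patterns and awn strokes;
awns are drawn on the image but excluded from the masks, mirroring the
annotation convention for real wheat heads. Clips render a larger latent
scene once and crop a drifting window, so frame *t*'s masks are exactly
frame 0's translated — the temporal coherence that motivates the exclusion
window.

What the simulator does **not** emulate: perspective, illumination
gradients, specularity, motion blur, cultivar variety, growth stages, or
annotation error. Passing tests therefore demonstrate that the pipeline's
machinery is correct and that its adaptation stages help under a controlled
synthetic-to-"real" shift; they do not certify performance on actual field
imagery.

## Numerical choices and degenerate inputs

- Masks on disk are 8-bit PNG {0,255}; loaders accept {0,1} and {0,255}
  and treat any nonzero pixel as foreground.
- Instance extraction from semantic masks uses 8-connectivity.
- Probabilities from `predict_probs()` are clamped to the open interval
  (1e−12, 1 − 1e−12).
- Images whose sides are not multiples of the network's divisor are
  zero-padded bottom/right and predictions cropped back.
- Fake-cutout placement uses rejection sampling (default 1000 attempts per
  template) and fails loudly when an image has no head-free region.
- `build_cutout_banks()` skips instances below 4 px (slivers of heads
  clipped at the frame border): they carry no texture and cannot survive
  geometric augmentation, which errors — deliberately — when a transform
  empties a footprint after its retry budget.
- Ties in model selection resolve to the earliest epoch (`which.min`).
- A non-finite training or validation loss aborts the stage with the epoch
  number (divergence error) instead of silently continuing.
- One global pipeline seed derives all stage seeds by fixed offsets, logged
  at startup; identical seeds give identical checkpoints (single-threaded).

## Problem sizes

The package's fixture-scale study conditions, used by the test suite and
the acceptance script, are: 60-frame clips of 96×96 frames, 4 background
frames, 200–300 training composites, the tiny encoder preset, 8–10 epochs
for stage S and 1–2 epochs for the adaptation stages, and full 360-rotation
expansions (the acceptance script thins stage G's expansion to every 2°).
Warm-started stages run 1–2 epochs; the Baseline, training from scratch on
the small few-shot set, needs ~4 epochs to leave the all-background
solution.
These sizes keep a complete pipeline run in CPU-minutes while leaving every
mechanism — synthesis, staged adaptation, selection, TTA, evaluation —
identical to a full-scale run, where one would use the `"base"` encoder,
10,000 composites and larger epoch budgets on real frames.

## Known limitations

- No video decoding: frames must be supplied as PNG directories (one frame
  per file, index in the filename).
- Single-class (binary) segmentation only.
- The training loop is single-threaded CPU; it is sized for the tiny
  preset and fixture images, not for training on real high-resolution
  datasets.
- Pseudo-labels are hard masks; no confidence weighting or curriculum.
- Geometric TTA (scales, flips with inverse warps) is out of scope; the
  implemented TTA is purely photometric.
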