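---
title: "Two-step vertebral landmark localization: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step vertebral landmark localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spinemark)
```

## The problem and the model

Sagittal spine radiographs are read by locating the four corners of each
vertebral body; endplate lines through those corners define the clinical
angles (L1–L5 and L1–S1 lordosis, sacral slope). `spinemark` automates
this with a coarse-to-fine pipeline of three convolutional networks:

1. **Presence (CNN 1 analogue).** The whole radiograph, resized to a fixed
   square and normalized to [0, 1], is mapped to 24 sigmoid outputs, one
   per level C2..S1. Training minimizes binary cross-entropy against the
   presence vector derived from the annotation (a level counts as present
   with at least two valid corner landmarks).
2. **Global corners (CNN 2 analogue).** A fully convolutional trunk ends in
   96 heatmap channels — 4 corners x 24 levels, in the fixed corner order
   upper-anterior, upper-posterior, lower-anterior, lower-posterior. Each
   channel passes through a DSNT head: spatial softmax, then the
   expectation of a coordinate grid spanning [-1, 1] with pixel centers at
   `(2i + 1 - n)/n`. The loss is the mean Euclidean distance between
   predicted and target normalized coordinates, restricted by a mask to
   the levels actually annotated in that image (and excluding the two
   undefined lower corners of S1). Masking is the only training semantics
   that does not fabricate targets for absent vertebrae.
3. **Refinement (CNN 3 analogue).** Per detected vertebra, the tight box
   around its step-I corners is grown by 70% per side (clipped to the
   image), cropped, resized, and passed to a single-vertebra DSNT network
   (1 x 4 x 2). Predictions are mapped back by the exact inverse of the
   recorded crop transform `p_out = (p - offset) * scale`. Growing each
   *side* by the extension fraction (rather than the box area) is the
   reading adopted here; the factor is a parameter (`extension`).

Angle definitions: all three angles are unsigned and folded into
[0°, 90°], computed from direction vectors (`atan2` of cross and dot
products) rather than slope coefficients, so vertical endplates need no
special case. This matches populations whose reported minima are 0° and
maxima stay below 90°; a signed convention for kyphotic segments would
need additional information the corner annotation does not carry.

## The synthetic data generator

No public dataset with vertebral corner annotations exists, so the
simulator is a first-class module, not a test fixture. It emulates:

- **Geometry.** Endplate slopes are constructed bottom-up from the sampled
  sacral slope; the L1–S1 angle is the sampled L1–L5 lordosis plus a
  lumbosacral disc wedge (uniform 7–20°, capped so L1–S1 < 90°); the
  lumbar rotation is spread over the 5 bodies and 4 discs with Dirichlet
  weights; thoracic levels add a mild kyphotic reversal. Corners are
  stored exactly where rendered, so the generator's angles are recovered
  by `angles_from_corners()` to well under 0.5°.
- **Population statistics.** Angles are drawn from truncated normals on
  the published supports (L1–L5 mean 36.3°, support [0.1°, 86.8°]; SS mean
  35.8°, support [0°, 89.4°]); standard deviations (16° and 12°) are
  chosen so the truncated means land near the published means — the source
  publishes mean and extremes but not the distribution shape.
- **Field of view.** The most-cranial visible level is drawn from T9..L1
  with weights (0.08, 0.26, 0.37, 0.25, 0.04) — the frequencies implied by
  the published per-level sample census, read as successive differences.
  The most-caudal level is S1; training-time caudal crops produce views
  ending at L3/L4/L5.
- **Appearance.** Bodies are bright convex quadrilaterals (Gaussian
  blurred, σ 0.8 px) over a mottled background; thoracic levels carry
  faint rib shadows and S1 a sacral wedge — the anatomical cues that make
  level identity decidable from the image, as on real radiographs.
  Artifacts: additive Gaussian noise (sd 0.03), collimation black borders
  (p 0.3, kept clear of the spine), brightness extremes (p 0.1), and
  instrumentation-like bright rod/screw strokes (p 0.1).
- **Scale.** Vertebra base height defaults to canvas height / 18 (a full
  T9..S1 column fits with margin), shrinking 3% per level cranially, with
  ±12% per-image scale jitter standing in for uncalibrated pixel spacing.

What it does **not** emulate: bone texture, fractures, spondylolisthesis,
soft tissue, true DICOM intensity statistics. Passing tests on synthetic
data therefore demonstrate that the pipeline's mechanics (level
assignment, corner regression, crop bookkeeping, angle arithmetic) work
end to end — not clinical-grade performance on real radiographs.

## Training recipe at test scale

The published full-scale recipe (200 epochs, ImageNet-pretrained ResNet-50
/ Inception-V3, lr 1e-4/1e-3, batch 16/8, plateau LR decay, best-validation
checkpointing) is kept as the default `train_schedule()` constants and the
plateau/checkpoint logic. The trainable backbone here is deliberately
tiny (`tiny-conv`, ~10^5–10^6 parameters): strided 5×5/3×3 convolutions,
coordinate channels appended to the input, a global-average-pool head for
presence (channel sums are translation-invariant count features — exactly
the evidence that determines the visible level run), and an extra stride-2
stage before the heatmaps so level assignment sees most of the column.

`fit_two_step()` trains the three nets for 10/10/6 epochs at lr 3e-3 on a
few hundred simulated images. The choices that matter for stability at this
scale and are the package's own:

- **Warm starting.** The corner nets' trunks are initialized from the
  trained presence net (and the refiner from the global net) — the
  in-package analogue of the original design's transfer learning, which
  is out of scope at full fidelity.
- **Box jitter for the refiner.** Training crops are jittered (extension
  ±0.35, offset up to 0.35 of the span) so the refiner tolerates the
  imperfect boxes step I produces at inference; without it, refinement
  inherits step-I's level-assignment errors.
- **Augmentation default.** The augmentation module (caudal crop,
  rotation/flip, elastic, noise) is fully implemented and tested, and
  available through the `augment` argument of every trainer; the short
  recipe trains without it, because at ~2,000 gradient samples invariance
  costs more accuracy than it buys. At full scale (hundreds of epochs) the
  trade reverses, which is why the original procedure uses it.

Typical test-scale results (200 training images, 50 held out, one CPU,
about 4 minutes): detection accuracy ≈ 0.94, median corner error ≈ 6% of
vertebra width after refinement versus ≈ 25% before — the same direction,
at larger magnitude, as the published full-scale step-I to step-II
improvement (2.20% → 1.98%).

## Numerical choices and degenerate inputs

- Coordinates are 0-based pixel centers, origin top-left, y down. The
  [-1, 1] normalization and its inverse are exact inverses of each other
  (`denormalize(grid_coordinate(i, n)) == i`).
- Whole-image resizing maps points by pure scaling (`p' = p * s`); the
  same convention is used for training targets and inference, so no
  half-pixel bias enters the pipeline.
- Resampling is bilinear (EBImage); the interpolation kernel is not an
  accuracy-relevant choice at these scales.
- The spatial softmax subtracts the channel maximum before
  exponentiation; heatmap channels must sum to 1 within 1e-4 before an
  expectation is taken, and masked loss terms with sub-1e-8 distances get
  zero gradient to avoid division blow-ups.
- S1: stored with its two upper corners valid; bounding boxes built from
  a near-collinear S1 endplate are padded to a minimum span before the
  70% extension, so the refiner crop never collapses.
- A caudal crop is accepted only if it slices no vertebra, removes at
  least one, leaves L3/L4/L5 most caudal and keeps `min_visible` (3)
  levels; after 50 rejected draws the image passes through unchanged.
- Rotations that would push a landmark off canvas are resampled (or
  skipped, per `oob_policy`).
- Horizontal flips swap the anterior/posterior corner roles within each
  endplate, keeping the four DSNT channels semantically fixed.
- The presence threshold defaults to 0.5; no contiguity constraint is
  imposed on detections by default (an optional longest-run filter
  exists), mirroring a design that demonstrably allowed mid-column
  misses.

## Known limitations

- The simulator's stylized appearance transfers none of the hard cases of
  real radiographs (fractures, osteophytes, overlapping bowel gas,
  extreme noise); tiny-backbone results quantify pipeline mechanics only.
- Standard backbone families (`standard-residual-50`,
  `standard-inception-v3`) are configuration-only: no pretrained weights
  are bundled, and constructing them for training raises an error.
- Angle errors at test scale are dominated by occasional off-by-one level
  assignments, which inflate maxima and depress R² — the same failure
  mode the original reports as missed vertebrae with propagated errors.
- Only PNG input is supported (no DICOM/JPEG reader in the dependency
  set); intensities are rescaled to [0, 1] by bit depth.
- The published y-axis weighted means are not reproducible from the
  published per-level y medians and counts (the x-axis ones are, exactly);
  the shipped reference table therefore anchors on the x columns.
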