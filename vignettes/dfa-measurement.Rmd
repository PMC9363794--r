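---
title: "Automated disc-fovea angle measurement: models, geometry, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated disc-fovea angle measurement: models, geometry, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

The disc-fovea angle (DFA) is the angle between the line joining the center
of the optic disc to the foveal center and the horizontal line through the
disc center. It is the standard objective index of ocular torsion: in
rotational strabismus the eye is cyclorotated and the DFA moves outside its
normal range. Measuring it from a color fundus photograph by hand is slow
and poorly reproducible, so `dfameter` automates the whole chain:

1. **Segment** the optic disc (class 1) and a *virtual macular area*
   (class 2) in the photograph with an encoder-decoder network.
2. **Localize** each structure's center as the center of the minimum
   enclosing circle of the largest connected component of its class.
3. **Compute** the signed angle from the two centers.

The virtual macular area deserves a word: the macula has no sharp visible
boundary, so the trainable label is a disc of fixed radius centered on the
fovea — 400 px at the native 2584 × 1985 camera resolution, scaled
linearly with image width at other resolutions (`400/2584` of the width).
This gives the network a well-defined target whose *center* is the
quantity of clinical interest.

## The angle

With disc center $(OX, OY)$ and macular center $(MX, MY)$ in image
coordinates (y growing downward), the magnitude is

$$\mathrm{DFA} = \arctan\!\left(\frac{|OY - MY|}{|OX - MX|}\right)\cdot\frac{180}{\pi},$$

defined as 90° when $OX = MX$, and the angle takes the opposite sign when
$MY > OY$ (fovea below the disc-center horizontal). `compute_dfa()`
implements exactly this; its tests pin down the limiting cases, the sign
rule, the $[-90, 90]$ range, mirror antisymmetry and translation
invariance.

## Center extraction

Predicted masks can fragment, so each class is first reduced to its
largest 8-connected component. Two center definitions are provided, since
both a "minimum outer circle" and a "minimum external (bounding)
rectangle" are defensible readings of common practice:

- `method = "circle"` (default): center of the minimum enclosing circle,
  computed with a randomized incremental Welzl-style algorithm (expected
  linear time; validated against an $O(n^4)$ pair/triple brute force);
- `method = "rectangle"`: center of the axis-aligned bounding box.

For the near-circular regions involved the two agree to within a pixel;
the circle is the default. No morphological smoothing is applied: center
fitting is robust to boundary jitter, and any cleanup would be an
undocumented extra modeling choice. Centers are kept at sub-pixel
precision; rounding happens only in reports.

## Segmentation models

The primary network is a DeepLabv3+-style encoder-decoder:

- **Encoder**: a MobileNetV2-style stack of 17 inverted-residual
  bottlenecks in the canonical stage plan (expansion 1 then 6; channels
  16/24/32/64/96/160/320 scaled by `width_multiplier`). The low-level
  feature tap sits after the first three bottlenecks (stride 4); the
  remaining 14 produce the high-level features. With `output_stride = 16`
  (default) the last stride-2 stage becomes a dilated stride-1 stage. A
  bottleneck adds its input to the convolution path exactly when the
  input and output shapes match — that condition is asserted in the test
  suite, both on the block table and functionally.
- **ASPP**: parallel 1×1, three 3×3 atrous branches at rates (6, 12, 18),
  and a global-pooling branch, concatenated and projected.
- **Decoder**: bilinear upsampling of the ASPP output to the low-level
  resolution, concatenation with a 1×1-projected low-level tap, two 3×3
  convolutions, a 1×1 classifier, and bilinear upsampling to the input
  size (3 output channels).

U-Net (4 down / 4 up levels, stride-2 convolution downsampling, bilinear
upsampling with skip concatenation) and PSPNet (stride-8 backbone with
pyramid pooling over bins 1/2/3/6) are included as comparison baselines in
canonical minimal form.

Because no deep-learning framework is assumed, the package ships its own
CPU training engine: im2col + BLAS convolutions, C++ kernels for the
depthwise and resampling operations, and hand-derived backward passes
that are verified against finite differences in the test suite.

Choices the underlying method leaves open, fixed here as package policy:

- **Normalization**: group normalization inside every conv block.
  It is independent of batch size — the right behavior at the small
  batches CPU training forces — and makes training and inference
  identical and fully deterministic.
- **Loss**: unweighted per-pixel softmax cross-entropy over the 3 classes.
- **Optimizer**: Adam (β₁ = 0.9, β₂ = 0.999); default learning rate
  5 × 10⁻⁵ and 100 epochs, matching the published full-scale protocol;
  batch size 4. The step size follows a linear warmup over the first two
  epochs and a cosine decay to 10% of the base rate.
- **Multi-start**: small networks trained from scratch occasionally start
  in a basin where the two structure classes never separate — typically
  every blob ends up labeled macula, at any learning rate. After
  training, if a structure class is absent from every validation
  prediction the run is declared collapsed and restarted from a reseeded
  initialization (up to four attempts; a collapsed attempt is abandoned
  at mid-training; the best non-collapsed attempt by validation loss is
  kept). The restart count is recorded on the fitted object.
- **Normalization of inputs**: images are `[0, 1]` per channel; no
  augmentation.
- **Checkpoint selection**: the epoch with the lowest validation loss,
  earliest epoch on ties (`select_best_checkpoint()` is a pure function
  of the history and is what `predict()` uses).
- **Argmax ties** break toward the lowest class index (background).

## Data protocol

`split_dataset()` shuffles ids with a seeded permutation and applies
floor arithmetic: `floor(N · 7/10)` train-pool vs test, then
`floor(|pool| · 9/10)` train vs validation. This reproduces the reference
counts exactly: 682 → 477/205 and 477 → 429/48.

Evaluation uses per-class IoU and pixel accuracy with unweighted means
(MIoU, MPA) over all three classes *including background*, plus the
Euclidean center errors DO (disc) and DM (macula) and min/max/average
summaries of per-image values. Per-image metrics are averaged by default;
a pooled-counts variant is available (`pooled = TRUE`) since either
convention is seen in practice. A class absent from both masks would make
IoU 0/0; it is scored 1.0 and flagged — "nothing to find, nothing found"
— though valid fundus images never trigger it. Center extraction and
DO/DM are computed at native image resolution by default (predicted masks
are upscaled nearest-neighbor), because the label protocol's 400-px radius
and the reported center errors are native-pixel quantities; a flag allows
network-resolution evaluation.

Images in which the model predicts no disc or no macula pixels are
recorded as `unmeasurable` with a diagnostic and excluded from angle and
center summaries — reported, never silently dropped.

## The synthetic-fundus generator

Real hospital datasets of this kind are private, so the package includes
a seedable generator that emulates the geometry the pipeline depends on:

- a bright elliptical disc placed nasally (semi-axes ≈ 9.0% and 8.2% of
  image width, ±5% seeded jitter — a typical disc size relative to a
  45° fundus frame);
- a darker radial falloff around the fovea, with scale tied to the
  macula label radius so the visual cue matches the label extent;
- the class-2 label disc of radius `400 · width / 2584` centered on the
  fovea (pixel-center rasterization, making the radius exactly measurable);
- quadratic-Bézier vessel arcs and Gaussian sensor noise (σ = 0.02 on the
  `[0, 1]` scale) as *unlabeled* nuisance structure;
- exact ground truth: centers are rounded to the pixel grid and the
  stored true angle is recomputed from the rounded centers, so the
  generator, the geometry stage and the angle stage are mutually
  consistent by construction.

Dataset draws use angles uniform in ±10° (spanning the normal DFA range)
and disc-fovea distances of 29–33% of image width (the disc-fovea
separation of a typical macula-centered photograph). The fovea sits
temporal (positive x) to the disc; a mirrored layout is available but off
by default, and disc outlines are ellipses — plausible idealizations
where the protocol is silent.

What the generator does **not** emulate: photographic texture, pathology,
illumination artifacts, camera vignetting idiosyncrasies, or anatomical
variation beyond the jittered geometry. Passing tests on synthetic data
therefore validate the *pipeline* — formulas, geometry, training
machinery, protocol arithmetic — not clinical performance on real
photographs.

## Validation strategy and problem sizes

The test suite layers independent oracles under every stage:

- minimum enclosing circles against an exhaustive pair/triple search
  (200 random point sets, agreement within 10⁻⁶);
- connected components against a plain flood fill;
- metric formulas against direct per-pixel recomputation;
- every backward pass against central finite differences;
- an end-to-end oracle: feeding ground-truth masks through the geometry
  and angle stages recovers the true DFA within 0.3° on 100 scenes —
  bounding the rasterization error and isolating the learned stage as
  the only other error source.

The learning experiment runs at desk scale: 64 training and 16 held-out
synthetic images at 128 × 128, `width_multiplier = 0.25`, 20 epochs of
Adam at a 10⁻² peak rate (the small-model, small-data regime tolerates
and benefits from a much larger step than the full-scale default; at the
full-scale rate the 320 desk-scale steps stop at a "mean fovea position"
solution that segments well but does not localize), batch 4, fixed seed. The
fitted model must reach held-out MIoU ≥ 0.7 and mean absolute DFA error
≤ 3°. These sizes keep a single-CPU run in minutes while still exercising
every architectural component; they are not a statement about
full-resolution performance.

## Known limitations

- Trained at desk scale the macula boundary is soft, so macula IoU trails
  disc IoU; center localization (what the angle needs) is much more
  accurate than boundary overlap.
- The CPU engine is single-threaded except for BLAS and is meant for
  validation-scale experiments, not 512 × 512 / 100-epoch production runs.
- The sign convention follows the image coordinate rule (negate when the
  fovea is below the disc-center horizontal) literally; mapping signed
  angles to clinical ex-/incyclotorsion additionally requires laterality,
  which the pipeline does not model.
- `resize_mask()` uses nearest-neighbor sampling; at extreme upscaling
  factors the blocky boundary slightly inflates boundary-sensitive
  metrics, but leaves center fits essentially unchanged.
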