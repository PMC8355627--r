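---
title: "Supervised multimodal section registration: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised multimodal section registration: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sectionalign)
```

## The problem

Histological section images of the same tissue acquired with different
staining techniques — here a Nissl-stained reference and an in-situ
hybridization (ISH) gene-expression section — must be brought into a common
coordinate system before they can be analysed jointly. Intensity-based
registration struggles on such pairs: the two modalities have unrelated
intensity distributions, and the soft tissue suffers elastic distortion,
tears and air bubbles. `sectionalign` implements a supervised alternative:
a network is trained on pairs with known dense deformations and learns to
predict, for a new pair, the per-pixel displacement field
`u(x, y) = phi(x, y) - (x, y)` mapping reference coordinates into the moving
image.

Throughout the package coordinates are 0-based pixel centres with `x` the
column index and `y` the row index; a displacement field stores the two
offset grids `(dx, dy)` in pixels and the transformation grid `phi = id + u`
is always derived, never stored.

## Field algebra

Everything downstream rests on a small algebra over dense displacement
fields:

* **Warping.** `warp_image()` resamples the moving image at `phi` with
  bilinear interpolation; samples leaving the image take the background
  value 0 (sections sit on a dark background) and outputs are clipped to
  `[0, 1]`. Labels are warped with nearest-neighbour sampling
  (`warp_labels()`) so region ids are never blended.
* **Composition.** `compose_fields(f, g)` evaluates
  `phi_c(p) = phi_f(phi_g(p))`, bilinearly interpolating `f`'s displacement
  components (not absolute coordinates) at the non-integer locations
  `phi_g(p)` and replicating displacements beyond the border. Replication
  avoids fabricating folds at the image edge during composition.
* **Inversion.** `invert_field()` inverts numerically by scattered data
  interpolation: each pixel `p` scatters the value `-u(p)` at its target
  location `p + u(p)`; the scattered samples are interpolated back onto the
  grid linearly over the triangulation induced by the deformed grid (each
  quad cell split into two triangles), with a nearest-site fallback outside
  the covered area. For smooth folding-free fields the round trip
  `compose_fields(f, invert_field(f))` has a mean interior residual well
  below half a pixel; folded regions are inverted best-effort.
* **Folding analysis.** `jacobian_determinant()` estimates `det J_phi` with
  central differences in the interior and one-sided differences on the
  border (a stencil that is exact for affine fields, borders included), and
  `corrupted_fraction()` reports the fraction of pixels where the
  determinant is non-positive — locations where the transformation folds or
  collapses.
* **Landmark interpolation.** `from_keypoints()` turns paired landmarks into
  a dense field by radial-basis interpolation of the displacements —
  thin-plate spline by default, multiquadric by flag, both with an affine
  polynomial term so that affine landmark configurations are reproduced
  exactly. A trained annotator typically places a few dozen landmark pairs
  per section, which is the regime the tests exercise.

## The registration network

The model has two stages, composed as `phi_hat = phi_global o phi_local`:

* a **global module** (spatial-transformer style) stacks the reference and
  moving images into a 2-channel input, reduces it with stride-2 3x3
  convolutions followed by dense layers, and regresses six affine
  parameters. The two translation outputs are scaled by `offset_gain`
  (default 20 px) so that a unit change of a raw parameter moves the section
  by a realistic amount — without this, translation recovery is far slower
  than shape recovery under RMSProp's roughly uniform per-parameter step
  sizes;
* a **local module** (encoder-decoder with skip connections) sees the
  reference stacked with the globally aligned moving image and predicts a
  dense elastic displacement. The flow output passes through
  `cap * tanh(z)` (default cap `0.35 * min(H, W)`), which bounds each
  component and keeps early training stable.

`init_identity()` zeroes the affine regression head and the flow
convolution, so an untrained network predicts exactly the identity — the
standard safe starting point for registration networks. The encoder halves
resolutions with ceiling division and the decoder crops after upsampling, so
any input of at least `2^depth` pixels per side works; divisibility by
`2^depth` is not required. Activations are leaky rectifiers (slope 0.1);
channel widths default to a VoxelMorph-like scale and are fully
configurable.

The network, backpropagation and the RMSProp optimizer are implemented
directly in R: convolutions are im2col gathers followed by BLAS matrix
multiplies, and the stride-1 input gradient is computed as a correlation
with the spatially flipped kernel (one more matrix multiply). The backward
pass — including the gradients through bilinear warping, through the field
composition, and through the perceptual backbone — is pinned by
finite-difference tests. Because the loss is only piecewise smooth (bilinear
sampling has derivative kinks at integer crossings, the endpoint error has
`|.|` kinks, and exactly-zero backgrounds sit on the leaky-ReLU kink), those
tests compare in bulk rather than entry-by-entry.

## The loss

Training minimizes an unweighted sum of three terms (weights are exposed for
ablation experiments but default to 1):

* **Image error** — the mean squared difference between the ground-truth
  registered image and the predicted one. The mean, rather than a plain
  squared norm, keeps the term resolution-independent and commensurate with
  the other terms, which an unweighted sum requires.
* **Endpoint error** — the squared normalized average endpoint error: the
  per-pixel Euclidean distances between true and predicted displacements are
  averaged, divided by a normalizer `T`, and squared, so a constant error of
  magnitude `d` scores `(d/T)^2`. `T` is the mean displacement magnitude of
  the training ground truths (about 20 px for full-scale section data) and
  is computed from the training split when not supplied.
* **Perceptual field loss** — the x and y components of the true and
  predicted fields are treated as images and compared through a
  convolutional feature extractor with channel-unit-normalized activations,
  squared differences averaged spatially and summed over layers. This term
  penalizes non-smooth, high-frequency disagreement far more than equally
  sized smooth disagreement, which is what pushes the network toward
  fold-free predictions without any explicit regularizer.

Both field losses are applied bidirectionally: the network is also run on
the swapped pair, and its output is compared against the numerically
inverted ground truth `u^{-1}`. The predicted inverse comes from the swapped
forward pass rather than from numerically inverting the prediction, because
scattered-data inversion is not smoothly differentiable and would block
gradient flow.

### The perceptual backbone

The classical choice of feature extractor is a pretrained VGG in its
LPIPS "lin" configuration. Pretrained weights cannot be assumed present, so
the default backbone is `"fixed-seed-random-conv"`: three 3x3 convolution
layers (8, 16, 16 channels, average-pooled between layers) whose weights are
drawn once from a fixed seed and then frozen — random convolutional features
are known to give usable perceptual distances. One design detail matters:
the filters are made **zero-mean**. Raw random filters respond mostly to the
local intensity level, which makes smooth perturbations look "larger" than
per-pixel noise after channel normalization — the opposite of perceptual
behaviour. Zero-mean filters are random band-pass/edge detectors, respond to
local structure, and robustly order dense per-pixel displacement noise above
equal-MSE smooth error across backbone seeds. A second detail is the
normalization floor `norm_eps` (default 0.1): channel normalization divides
by `sqrt(sum of squared activations + norm_eps^2)`, so that in flat field
regions — where zero-mean filters produce near-zero activations — the
normalized features are damped instead of being blown up into arbitrary
unit vectors. Without the floor, the distance between two nearly identical
smooth fields is dominated by amplified micro-differences and cannot
approach zero as training converges. Displacement components are
divided by `input_scale` (typically `T`) and clamped to `[-3, 3]` before
entering the network; fields must be at least 32x32. The
`"pretrained-vgg-lin"` flavour is constructed from a user-supplied directory
of NPY weight files and errors informatively without one.

## Synthetic study conditions

The generator emulates the structure of a Nissl/ISH section-pair corpus so
that every downstream stage is testable without external atlas data:

* **Geometry.** A smooth star-shaped section outline (ellipse with low-order
  radial harmonics) whose size and shape vary continuously with the coronal
  section index over the range 1-528, peaking mid-brain.
* **Modalities.** The reference is rendered as mid-bright tissue with fine
  cellular speckle (pseudo-Nissl); the moving image shows the same geometry
  as dark tissue with sparse bright puncta whose density and size depend on
  the gene tag (pseudo-ISH, seven default genes). A perfectly registered
  pair still differs by more than 0.2 mean absolute intensity on the
  foreground, so naive intensity matching cannot shortcut the task.
* **Deformations.** The ground truth composes an affine map (translation up
  to 20 px, rotation up to 10 degrees, axis scales in [0.85, 1.15], all at
  full 320x456 scale and scaled proportionally for smaller frames) with a
  smooth elastic part interpolated from perturbed edge control points
  (6 px amplitude at full scale). Under these defaults the dataset-level
  mean displacement magnitude lands near 20 px at full scale — the value
  used as the endpoint-error normalizer. The moving image is rendered by
  warping the in-reference-frame ISH rendering through the numerically
  inverted truth, and the generator self-checks folding-freeness, foreground
  overlap (Dice at least 0.95) after registration, and multimodality,
  resampling on failure.
* **Artifacts.** Tears (thin dark polylines) and air bubbles (bright discs
  with dark rims) can be painted onto the moving image; they corrupt
  appearance only, never geometry.

What passing these conditions does *not* show: real ISH sections have
staining gradients, partial sections, non-smooth expert corrections and
acquisition noise that the generator does not emulate, so results on the
synthetic suite demonstrate correctness of the machinery, not expected
accuracy on atlas data.

The two augmentation families mirror training practice: photometric
augmentation (blur, brightness, gamma, additive noise, each applied with
probability 1/2) leaves the ground truth untouched; elastic augmentation
samples control points on the section boundary of the moving image,
perturbs them (up to 8% of the smaller image side by default, hard-capped at
15%), interpolates a smooth warp `psi`, and updates the sample as
`moving' = moving o psi`, `truth' = psi^{-1} o truth`. The composition order
is fixed by the warp-consistency identity — warping the augmented moving
image by the augmented truth must reproduce the original registered image —
which the test suite asserts on every accepted sample. Folded `psi` (or
folded augmented truths) are rejected and resampled.

## Training and evaluation protocol

Training uses RMSProp with learning rate `1e-3`, forgetting factor `0.9`
and batch size 4. Two split schemes are provided: a stratified train/test
split by gene and anterior-posterior tercile (sections 1-176, 177-352,
353-528; within each stratum the test share deviates from the requested
fraction by at most one sample), and a gene-holdout split for testing
generalization to unseen genes.

Evaluation mirrors the annotation geometry: the reference-space
segmentation is warped into *moving* space by the numerically inverted
truth and the numerically inverted prediction, and the two are compared with
a pixel-weighted hierarchical Dice score. Level 0 separates background from
foreground; deeper levels split the section into nested subregions (the
synthetic hierarchy splits by left/right position, radial bands and vertical
position down to level 4; requested levels clamp to the hierarchy depth).
Class weights come from the truth-warped side's pixel counts — the
convention matters only for asymmetric pairs and is stated here once. The
corrupted-pixel percentage of the predicted field completes the report.

## Numerical choices and degenerate inputs

* Bilinear sampling uses zero background for images/labels and edge
  replication for displacement lookups; nearest-neighbour rounding follows
  R's `round()`.
* The RBF system solves with a dense LU; coincident reference landmarks are
  rejected (singular system), as are fewer than three landmarks.
* SDI inversion raises an inversion-failure error when the deformed domain
  degenerates (all triangles collapse); outside the deformed domain the
  nearest scattered site is searched on the image of the grid boundary,
  where it must lie for folding-free fields.
* Endpoint-error gradients guard the `|.|` kink with a `1e-12` floor;
  channel normalization in the backbone adds `1e-10` inside the square
  root.
* Image grids below 8x8 are rejected throughout (the network downsamples
  repeatedly), and the perceptual loss requires at least 32x32.

## Problem sizes in the test suite

The shipped tests run the full pipeline at desk scale, chosen so the whole
suite completes comfortably on one CPU: section pairs of 80x114 (a quarter
of the production 320x456 frame per axis, with displacement amplitudes
scaled accordingly) down to 32x48 for training runs; an overfit run of 500
RMSProp steps on eight 64x96 pairs; translation-recovery training with the
local branch frozen on 48x64 pairs; and a three-seed perceptual-ablation
comparison on 32x48 pairs. Channel widths in these runs are smaller than
the production defaults; the contracts they check (loss decrease, Dice,
folding, recovery error) do not depend on the widths. The full-scale
mean-displacement calibration is checked on a modest number of 320x456
samples, since per-sample means concentrate tightly around the target.

## Known limitations

* 2D only: the perceptual loss is defined on images, and nothing here
  generalizes it to volumes.
* No diffeomorphic guarantee: smoothness is encouraged by the loss, not
  enforced by construction; `corrupted_fraction()` is the watchdog.
* The SDI inverse is linear-interpolation accurate and degrades in folded
  regions.
* The random-conv perceptual backbone is a stand-in with the right
  qualitative behaviour; a pretrained VGG-lin backbone, where available,
  remains the reference choice.
* Training at the production 320x456 resolution is possible but slow in
  plain R; the package targets desk-scale experimentation and method
  validation.
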