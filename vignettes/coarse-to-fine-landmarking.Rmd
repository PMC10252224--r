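---
title: "Coarse-to-fine volumetric landmarking of 3D facial surfaces"
author: "facemark3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine volumetric landmarking of 3D facial surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(facemark3d)
```

## The problem

Facial soft-tissue landmarks — pronasale, cheilion, gonion and their kin —
anchor orthodontic measurement, orthognathic surgical planning and facial
asymmetry analysis. Stereophotogrammetric scanners deliver dense, sub-mm 3D
surface models, but placing the landmarks on those models is still largely a
manual task: slow, operator-dependent, and poorly repeatable. facemark3d
implements an automatic two-stage ("coarse-to-fine") localizer that works
directly on the 3D point cloud rather than on 2D projections of it, so no
geometric information is lost to a rendering step.

The package covers 32 named landmarks, grouped into six facial regions
("organs"): eyes (8 landmarks), nose (7), lips (7), chin (4), right face (3)
and left face (3). Ten landmarks are left-right pairs; twelve are midline
points. `landmarkRegistry()` is the single source of truth for names,
abbreviations, region assignment and ordering; the ordering fixes the layout
of every network output vector and is part of the package contract.

## Representation

A scan is a K x 3 matrix of mm coordinates with K varying between scans. To
obtain a fixed-size network input the cloud is

1. normalized into $[-1, 1]^3$ by an *isotropic* map: translation $t$ = the
   bounding-box midpoint, scale $S$ = half the largest bounding-box edge
   (mm per normalized unit);
2. voxelized onto an $M^3$ binary occupancy grid: a point with normalized
   coordinate $c$ falls in cell $\lfloor (c+1)/2 \cdot M \rfloor$ per axis,
   clamped so the $c = +1$ boundary belongs to the last cell.

The scale $S$ is recorded with every cloud. It is what restores mm units:
the evaluation metric for a landmark is
$L = S\sqrt{(x-\hat x)^2 + (y-\hat y)^2 + (z-\hat z)^2}$, the Euclidean
distance in the shared normalized frame times the scaling multiplier. An
isotropic $S$ is a requirement, not a convenience: with per-axis scales the
restored distance would not be a single multiplication. The grid resolution
bounds the representation error at $2S/M$ mm per axis; this bound is
property-tested in the suite for $M \in \{2, 8, 32, 200\}$.

Both of these choices — isotropic scaling and half-open binning with an upper
clamp — were genuinely open design points; the alternatives (per-axis
scaling, nearest-cell rounding) either break the mm restoration or leave the
$+1$ boundary unassigned.

## The two stages

**Detection.** A volumetric network maps the $M^3$ occupancy tensor to six
boxes, one per region, each encoded as $[x, y, z, xl, yl, zl]$: center plus
per-axis center-to-face half-extents, 36 values in all. The body is a stack
of blocks, each 3D convolution ($3^3$ kernel, stride 1, pad 1) →
$2^3$ max pooling → batch normalization → sigmoid, followed by a flatten and
a dense head with a linear 36-unit output. Raw outputs are decoded with
tanh (centers onto $(-1,1)$) and softplus + $10^{-3}$ (half-extents strictly
positive), so an invalid box is unrepresentable; the decoder was left open
by the architecture description and this is the package's resolution. The
training loss averages, over the six regions, a weighted sum of squared
center error and squared half-extent error with weights
$\lambda_1 + \lambda_2 = 1$ (default 0.5/0.5; the weights are tunable). A
printed variant of the size term as a difference of squares is available as
`sizeTerm = "diff_of_squares_abs"`; it is not the default because the
difference of squares is sign-indefinite and only its absolute value yields
a usable loss.

**Prediction.** Each region is cropped from the normalized cloud with its
(detected or ground-truth) box, half-extents multiplied by a margin (default
1.1) to tolerate detection error, then re-normalized to its own
$[-1, 1]^3$ frame and re-voxelized. The margin and the open-ended crop
question — should training crops use ground-truth or detected boxes? — are
resolved as: ground-truth boxes during training, detected boxes at
inference. Each region has its own network: the same conv/pool/norm/sigmoid
cycles, then a stage of eight two-convolution volumetric residual blocks
(an 18-layer-style residual layout transposed to 3D), then a dense head with
a linear $3N$ output, $N$ the region's landmark count. The residual blocks
are *pre-activation* (`x + conv(relu(bn(conv(relu(bn(x))))))`) with the
second convolution zero-initialized, so a fresh stage is an exact identity;
a post-addition activation would break that property. The stage keeps one
spatial resolution and width because after the pooling cycles the grid is
too small to stride down four more times. All residual weights are randomly
initialized: 2D pretrained weights do not transfer to volumetric kernels,
so pretraining is deliberately not emulated.

Prediction targets are the region-frame coordinates in $[-1,1]$ — the same
frame as the cropped input, which keeps losses comparable across regions.
The loss is the convex combination
$\lambda_1 L_{\text{mean}} + \lambda_2 L_{\text{max}}$ of the mean and the
maximum squared landmark distance (defaults 0.5/0.5): the mean term drives
the average error down, the max term the worst case. The combination always
lies between its two ends, an identity the tests assert. Note the training
losses operate on squared distances; only the evaluation metric takes the
root and restores mm.

At inference the composed transforms (region frame → face frame → mm) map
each region's predictions back to the original coordinate system, so the
output is always the full 32-landmark set in mm.

## The synthetic cohort

No public scan corpus covers these 32 landmarks, so the package ships a
parametric generator whose ground truth is exact by construction. A face is
a height field over an elliptical domain: a half-ellipsoid head (default
half-axes 70 x 95 x 80 mm) plus smooth Gaussian features — a nose ridge,
two eye bulges, two lip lobes and a chin boss. All 32 landmarks are placed
at fixed parametric positions and evaluated through the same height
function, so they lie exactly on the noise-free surface. Afterwards the
whole face (points and landmarks alike) passes through a smooth left-right
asymmetry warp and a pose rotation; isotropic Gaussian measurement noise
(default sd 0.3 mm, the order of stereophotogrammetric error) is added to
the sampled points only, never to the recorded landmarks. Sampling is
area-weighted uniform (rejection on the surface-area element), emulating the
dense even coverage of optical scanners. K defaults to 20000 points per
face.

Ground-truth region boxes are derived from the landmarks: the per-region
landmark bounding box in the face's normalized frame, each half-extent grown
by a quarter of the box diagonal (split evenly across both sides) and
floored at 0.05 normalized units. The derivation is a package choice — how
detection ground truth is produced from annotated landmarks is exactly the
gap a synthetic cohort must fill — and every box-quality figure is relative
to this construction.

What the generator does *not* emulate: real craniofacial shape statistics,
skin texture, occlusions (hair, hands), holes and scanning artifacts. Tests
passing on synthetic faces demonstrate that the machinery — representation,
networks, losses, frame bookkeeping — works end to end and that the
networks can learn the mapping; they do not certify clinical accuracy.

## Training and problem sizes

Training uses Adam (default learning rates 3e-3 for detection, 1e-3 for
prediction) on minibatches of up to 10, with per-epoch loss histories and
optional checkpointing. When a validation split is present, both trainers
track the validation loss, return the best-validation checkpoint rather than
the final epoch (a practical rendering of "stop a little before
convergence"), and can stop early after a configurable patience; with no
validation faces they simply train for the full epoch budget. Everything is deterministic under a fixed seed on
one device: seeds drive weight initialization, minibatch shuffling, and the
generator. Full-scale defaults mirror the study settings ($M = 200$, 600
detection epochs, 500 prediction epochs per region, 500 faces, 7:2:1
train:test:val split, floor-based with the remainder to train).

The test suite and the acceptance script run a scaled version of the study
chosen as the package's own single-CPU working point: 60 training and 20
held-out faces at $M = 32$ (face and region grids alike), 8000 points per
face, noise sd 0.3 mm, detection channels 4/8/16 for 60 epochs, prediction
channels 4/8/8 with 8 residual blocks for 25 epochs per region. At this
scale the trained pipeline is compared against the box-center baseline
(predicting each region's ground-truth box center for all of its landmarks)
and the detector against the ground-truth boxes by volumetric IoU. The
recovery checks are run at three fixed seeds with a majority rule, because
individual training runs are stochastic by nature.

## Numerical notes and degenerate inputs

* All-identical clouds cannot be normalized ($S = 0$) and are rejected;
  clouds need at least 4 points at load time, 2 distinct points to
  normalize.
* An empty region crop raises a typed condition naming the region; the
  inference path retries once with a 1.5x margin before failing.
* Batch normalization uses batch statistics during training (momentum 0.1
  running updates) and stored running statistics in evaluation mode, which
  makes inference exactly deterministic.
* The max-loss gradient follows the (first) argmax landmark — the standard
  subgradient choice; ties are measure-zero under continuous inputs.
* Training aborts with a diagnostic on a non-finite loss rather than
  continuing silently.
* "±" figures in summaries are sample standard deviations ($n-1$).
  Threshold coverage ("fraction within 2.5 mm") is computed over
  per-landmark mean errors (primary, matching how such figures are usually
  quoted) and, secondarily, over individual face x landmark errors; box-plot
  statistics use the Tukey convention.

## Limitations

* The backprop engine is intentionally minimal (the layers this
  architecture needs, nothing else); it is single-device and CPU-oriented.
* Detection is direct box regression — no anchors, no proposals — exactly
  as designed; it relies on faces being normalized into a canonical cube.
* Landmark definitions in the registry are short textual summaries of
  standard anthropometric definitions, not a substitute for a clinical
  protocol.
* Graph networks, transformers and heatmap regression are out of scope.
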