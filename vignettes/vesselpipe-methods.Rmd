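---
title: "Blockwise vessel segmentation and morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blockwise vessel segmentation and morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whole-organ fluorescence microscopy of vasculature produces volumes far too
large to segment in one piece, and the signal itself is heterogeneous:
endothelial (wall) labeling makes large vessels appear as bright hollow
tubes with a dark central lumen, while capillaries are dim, thin, solid
tubes with complex branching, over a diffuse background contaminated by
isolated fluorescent specks.  `vesselpipe` implements a complete pipeline
for this setting: overlapped blocking of TIFF slice stacks, a lightweight
multi-resolution 3D convolutional network for per-block segmentation,
OR-fusion of block masks, plane-wise morphological lumen filling with
small-component removal, topology-aware evaluation metrics, and centerline
morphometry, together with a synthetic phantom generator that provides
ground truth for training and validation without any external data.

## Blocking and fusion

Volumes are split into fixed-size blocks (default 192^3 voxels) with a
fixed overlap (default 32) between neighbours.  Per axis, block origins
advance by `block - overlap`; a final block that would overrun is clamped
to end exactly at the volume edge, gaining extra overlap, so every block
is network-shaped.  Only when an entire axis is shorter than the block
size is the block zero-padded, and fusion trims the padding before
combining, so padding can never leak foreground.  Overlapping voxels fuse
by logical OR: for a binary pointwise decision this makes blockwise
prediction followed by fusion *exactly* equal to whole-volume prediction
wherever blocks agree, and favours recall where they disagree.  All
coordinates are 0-based `(z, y, x)` with half-open extents, matching slice
-stack indexing; the block layout is recorded in a plain-text coordinate
file that round-trips to the same grid.

Parallelism is expressed as a deterministic map over independent work
items (blocks) whose results merge in item order, so the output is
bit-identical for any worker count.  Post-processing operates on the fused
volume, not on per-worker pieces, which removes the need to reason about
halo sizes for the fill operations (a slice-family fill can have
volume-wide reach).  Overlapped z-sections (`plan_sections`) remain
available for parallel slice I/O.

## The segmentation network

The network extracts features at three resolutions.  Scale *k* (0-based)
average-pools the input by 2^k, lifts it to a per-scale channel width with
a 3^3 convolution, and applies BottleConv -> LinkConv -> BottleConv:

* **BottleConv(W)** squeezes channels with a 1x1x1 convolution (ratio 2),
  convolves 3^3 at the reduced width, expands back, and adds the input —
  a bottleneck residual unit that deepens the network at minimal
  parameter cost.
* **LinkConv(W)** is a one-level U-Net inside the branch: pool by 2,
  two 3^3 convolutions at doubled width, a stride-2 transposed
  convolution back up, concatenation with the unpooled input, and a
  fusing 3^3 convolution.

Branch outputs are upsampled to full resolution by k successive stride-2
transposed convolutions, concatenated, reweighted by CBAM (channel
attention via a shared two-layer MLP over global max- and average-pooled
channel vectors with reduction 6, then spatial attention via a 7^3
convolution over the channelwise max and mean maps), and reduced to a
single sigmoid output by two 3^3 convolutions (head width 24, then 1).

The published description of this architecture fixes its parameter budget
(0.15M) but not the exact channel widths; the widths used here —
(8, 12, 16) across scales, LinkConv expansion 2, bottleneck ratio 2,
attention reduction 6, head 24 — were chosen so the closed-form parameter
sum lands at 146,662 (0.15M at two significant figures, under 1% of a
16.42M-parameter 3D U-Net).  `count_parameters()` counts the actual
arrays and is tested against the closed-form sum.  Whether the original
branch upsampling used transposed convolution or interpolation is not
recoverable from the text; transposed convolution is declared normative
here, and the same applies to the exact per-branch layer counts.

All convolutions use symmetric "same" zero padding so output shape equals
input shape; activations are ReLU except the final sigmoid.  Input patch
edges must be divisible by 2^n_scales (the deepest branch pools once more
inside LinkConv).  There is no normalization layer; instead each input
block is min-max normalized to [0, 1] with an epsilon guard for constant
blocks.  The final bias is initialized to -2 so an untrained network
starts near the background prior, which stabilizes early training under
class imbalance.

The forward and backward passes are implemented in compiled code
(im2col patch matrices contracted through BLAS).  The contraction runs in
single precision — each output element sums at most ~1000 products of
O(1) activations and weights, so float keeps about six significant
digits while halving memory traffic — and every gradient is verified
against central finite differences in the test suite.  One
subtlety documented there: with zero-initialized biases whole feature
maps sit exactly on the ReLU kink, where the loss is genuinely
one-sided-differentiable; the finite-difference check therefore nudges
biases off zero first.  Training itself uses the standard subgradient
choice relu'(0) = 0.

## Training protocol

Adam (beta1 0.9, beta2 0.999), initial learning rate 0.001 dropping to
98% of its previous value every 10 epochs (`lr0 * 0.98^floor(e/10)`), and
voxelwise binary cross-entropy.  Augmentation: random crop to the
training patch shape, random permutation of the three spatial axes, and a
random multiplicative brightness factor drawn from [0.7, 1.3], applied
to the raw crop *before* the input normalization, as brightness models
acquisition-gain variability of the raw data (the range is this
package's choice; only the augmentation kinds are prescribed).  Validation Dice is computed
each epoch on the centered training-patch-sized crop of each validation
block — full-block validation at every epoch would dominate desk-scale
runtime — with the prediction lumen-filled first: ground truth includes
lumens the raw network cannot see locally, so the filled prediction is
the quantity the pipeline's Dice is actually measured on, and selecting
the best epoch on raw Dice instead favours epochs that happen to leak
probability into lumens over epochs with cleanly closed walls.  The
weights of the best validation epoch are returned.  Training is
deterministic for a fixed seed.

Desk-scale problem sizes used by the test suite: datasets of 60 blocks of
64^3 voxels cropped from 128^3 phantoms (70/15/15 split, about a quarter
background-only), the width-halved configuration (4, 6, 8; head 12),
30 epochs of single-sample steps on random 40^3 crops.  Crop size follows
the receptive field: the pooled branches of the multi-scale network need
spatial context (40^3 measurably improves wall placement over 32^3,
whose windows fit entirely inside the largest lumens), while the
one-scale ablation variant trains on 32^3 crops its small receptive
field can actually exploit.  These sizes keep a
full training run in the ten-minute range on one CPU core while leaving
the architecture, schedule and loss untouched; final evaluation runs a
held-out 128^3 phantom volume through the complete pipeline (blocking,
prediction, OR fusion, hole filling, component removal).

## Post-processing

A network that sees only a block of a large vessel cannot know the dark
lumen is interior — but it segments the wall reliably.  After fusion the
lumen is a cavity that is usually *open* at the volume or vessel ends, so
a single 3D hole fill (which keeps any background component touching the
volume border) does nothing.  Plane-wise filling solves this: every
interior cross-section of a closed tube is an annulus, so 2D filling over
the x-y, x-z and y-z slice families — repeated twice, six passes in all —
fills tube lumens regardless of their 3D openness.  One 2D fill converts
to foreground every background region of a slice not 4-connected to the
slice border (foreground-8 / background-4 duality per slice); 3D
components for the removal stage use 26-connectivity.  Components with
strictly fewer voxels than `min_size` (default 100; the threshold is
configurable, as no specific value is prescribed) are removed, eliminating
isolated speckles, since real vessels form a connected network.  The order
is fill-then-remove: filling can lift a below-threshold wall fragment
above the size threshold, and removal-first would delete it — the test
suite constructs a thin hollow shell where the two orders provably differ.
Filling is extensive, removal anti-extensive and idempotent, and both are
shift-equivariant away from borders; all are property-tested against
brute-force flood-fill and BFS-labeling oracles.

## Metrics

Voxel overlap: precision, recall, Dice `2TP/(2TP+FP+FN)` and Jaccard,
with the empty-empty convention of 1.0 and empty-vs-nonempty 0.0.
Centerline Dice (clDice) is the harmonic mean of topology precision
(fraction of the prediction's skeleton inside the truth) and topology
sensitivity (fraction of the truth's skeleton inside the prediction);
it punishes missing or spurious branches far harder than wall-thickness
errors.  The Hausdorff distance is the symmetric maximum
nearest-surface-voxel Euclidean distance, computed exactly via distance
transforms, in voxel units, with an optional percentile variant (HD95).
The originating publication keeps its metric formulas in supplementary
material; the standard definitions above are declared normative for this
package, and its printed Hausdorff value carries no unit, so no numeric
Hausdorff target is asserted anywhere.

## Skeletonization and morphometry

Skeletons come from sequential topology-preserving thinning: six
directional sub-iterations delete border voxels that are *simple points*
(topological numbers T26 = 1 and T6 = 1, checked directly on the 3x3x3
neighbourhood) and not path endpoints, until stabilization.  Because each
deletion is of a simple point, the skeleton has exactly as many connected
components as the mask.  Thinning necessarily rounds off tube end caps
(the true medial axis of a capped cylinder stops about one radius short
of each cap), so skeleton endpoints are then prolonged along their local
chain direction to the mask boundary; this recovers full tube lengths —
axis-aligned tubes within 5%, 45-degree oblique tubes within 10% — at the
price of counting centerline up to the cap, which is the convention a
length-density measurement wants.  The skeleton graph connects
26-neighbouring skeleton voxels; redundant triangle chords (an edge whose
two endpoints share a strictly-closer common neighbour) are pruned so a
straight digital line has interior degree 2.

Node radii are the Euclidean distance transform of the mask evaluated at
skeleton voxels, scaled to micrometres (recovered within half a voxel on
cylinders of radius 2-10).  Morphometry reports total centerline length
(sum of Euclidean edge lengths), length density (mm per mm^3 of region),
bifurcation count (nodes of degree >= 3) and density, a per-1-um radius
histogram (per node; the source work does not state its binning, and
1 um bins over nodes are this package's convention), and the number of
connectivity domains (skeleton graph components, ids in decreasing size
order).  SWC export writes the standard 7-column format, type code 7,
coordinates in micrometres, one root per domain, parents before children.
Vascular loops are legal in the skeleton graph but not in SWC, so each
cycle is broken at its lowest-radius edge (maximum spanning tree on the
minimum endpoint radius) and the break count is recorded in a header
comment.

## The phantom generator

The generator emulates the appearance properties the pipeline depends on,
with all randomness routed through explicit seeds (saved and restored
around every stochastic operation, so no global RNG state leaks):

* centerlines are seeded random walks with Gaussian direction
  perturbation and probabilistic symmetric bifurcation (child radii
  scaled by 2^(-1/3), a Murray-law-like taper; radii never increase from
  root to tip);
* tubes with radius >= 6 um render wall-only: an annulus of 2 um wall at
  the bright intensity with the lumen left at background level, so it is
  indistinguishable from background, as under wall-only labeling; thinner
  tubes render solid at a dimmer intensity (bright large vessels, dim
  capillaries);
* ground truth is the filled tube, lumen included;
* corruption adds the background offset, Gaussian noise, and isolated
  bright speckle blobs rejection-sampled so that neither they nor their
  1-voxel border touches the truth mask or each other — giving
  component-removal tests unambiguous expected outcomes;
* a Gaussian blur stands in for the PSF.

Default appearance values (wall 200, capillary 120, background 40 +/- 10
on an 8-bit scale, PSF sigma 0.7 um) are plausible stand-ins chosen once
— the source data's intensity distribution and SNR are not published — and
the defaults for geometry (radii 2-20 um, hollow threshold 6 um, wall
2 um) follow the stated tissue properties.  What the phantom does *not*
emulate: anisotropic PSFs, stripe or stitching artifacts, intensity
attenuation with depth, arterial/venous identity, and truly
capillary-dense networks.  Tests passing on phantoms therefore validate
the pipeline's mechanics and its behaviour under the stated appearance
model, not segmentation accuracy on real tissue.

## Numerical and design choices

* Binarization threshold 0.5 (the canonical BCE operating point),
  exposed as a configuration flag.
* Binary masks are stored on disk as 8-bit {0, 255} TIFF, LZW-compressed;
  in memory they are 0/1 integer arrays.
* Resampling is integer-factor block-mean pooling for images; binary
  masks take a majority vote with ties resolved to foreground.
* Edge blocks are clamped, not partially emitted (the network needs fixed
  input shapes); whether the original implementation clamps or pads is
  unknown — clamping is this package's choice.
* Degenerate inputs: empty masks skeletonize to empty skeletons; empty
  regions make densities an error rather than NaN; Hausdorff distance on
  an empty mask is an error; constant blocks normalize to zero.
* Block prediction caches are content-complete-or-absent (written via a
  temporary file and atomic rename), so a crashed run resumes without
  recomputing finished blocks.

## Known limitations

Very large vessels whose walls are broken in the prediction cannot be
closed by hole filling and would require manual correction; the
morphometry assumes an isotropic or mildly anisotropic voxel grid; the
trained desk-scale networks here are demonstrations on phantom data, not
models for real brains; and MAC-count reproduction is out of scope since
the input size underlying the published operation count is ambiguous.
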