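# vesselpipe

Blockwise segmentation and morphometry of vasculature in large 3D
fluorescence volumes, in R.

## The problem

High-resolution fluorescence microscopy of whole organs images blood
vessels across four orders of magnitude in size — from arteries hundreds
of micrometres wide down to 2–3 µm capillaries — in volumes far too large
to process at once. Endothelial (vessel-wall) labeling complicates
segmentation further: large vessels appear as bright hollow tubes whose
dark lumen looks exactly like background, while capillaries are dim solid
tubes, and the background carries isolated fluorescent specks.

`vesselpipe` is a complete pipeline for this setting, aimed at
computational neuroscientists and microscopists working with TIFF slice
stacks:

1. **Overlapped blocking** — the volume is split into fixed-size blocks
   (default 192³) with a 32-voxel overlap; block origins are clamped at
   volume edges and recorded in a plain-text coordinate file.
2. **A lightweight three-scale segmentation network** — features are
   extracted at full, 1/2 and 1/4 resolution; each branch runs
   BottleConv (bottleneck residual) and LinkConv (a one-level U-Net)
   units, branches are fused by a CBAM attention block, and a two-layer
   head emits voxel probabilities. The reference configuration has
   146,662 trainable parameters (0.15M — under 1% of a 16.42M-parameter
   3D U-Net).
3. **OR fusion** of overlapping block masks, which makes blockwise
   prediction exactly transparent for pointwise decisions.
4. **Morphological post-processing** — six plane-wise 2D hole-filling
   passes (x–y, x–z, y–z, twice) close vessel lumens that a 3D fill
   cannot, and 26-connected components below a size threshold are
   removed.
5. **Evaluation** — precision, recall, Dice, Jaccard, centerline Dice
   (clDice) and exact Hausdorff distance.
6. **Morphometry** — topology-preserving skeletonization, per-node radii
   from the distance transform, length and bifurcation densities,
   connectivity domains, and SWC export.
7. **A synthetic phantom generator** producing vascular volumes with
   known ground truth that reproduce the wall-only appearance model, so
   the whole pipeline can be trained and validated without external
   data.

The segmentation network, its training loop (Adam, BCE, learning rate
0.001 dropping to 98% every 10 epochs, crop/transpose/brightness
augmentation) and all 3D morphology are implemented natively (Rcpp +
BLAS); no deep-learning framework is required.

## Worked example

Generate a phantom, train a small network, segment a held-out volume and
analyze it:

```r
library(vesselpipe)

# a 128^3 phantom with 6 vessel trees, wall-only large vessels, noise
spec <- phantom_spec(shape = c(128, 128, 128), n_trees = 6, seed = 101)
ds   <- make_dataset(spec, n_blocks = 60, block_shape = c(64, 64, 64),
                     seed = 101)

net <- build_network(net_config(branch_widths = c(4, 6, 8),
                                head_width = 12), seed = 2)
res <- train_network(net, ds, train_config(epochs = 30,
                                           patch_shape = c(40, 40, 40),
                                           seed = 5))

held <- generate_phantom(phantom_spec(shape = c(128, 128, 128),
                                      n_trees = 6, seed = 777))
ck <- tempfile(fileext = ".rds"); save_checkpoint(res$net, ck)
seg <- segment_volume(pipeline_config(checkpoint = ck, block_shape = 64,
                                      overlap = 32), volume = held$image)
evaluate_segmentation(seg$mask$voxels, held$truth$voxels)
#>   precision    recall      dice   jaccard    cldice       hd
#> 1  0.863903 0.9740491 0.9156756 0.8444664 0.9709315 9.380832

sk <- skeletonize(seg$mask$voxels)
sk <- estimate_radii(seg$mask$voxels, sk)
morphometry(sk)
#> <morphometry> length 2.5877 mm (1233.9 mm/mm^3), 99 bifurcations
#> (47206.9 /mm^3), 2 domain(s)
```

The Dice of 0.92 says that after lumen filling the predicted vessel
volume agrees with the ground truth to within a sub-voxel wall-placement
error; the clDice of 0.97 says essentially every centerline branch was
recovered (recall 0.97 of truth skeleton inside the prediction and the
prediction's skeleton almost entirely inside the truth).  The densities
are those of this deliberately vessel-dense phantom, not of real
tissue.  These numbers were printed by the code above on one CPU core;
training takes roughly a quarter of an hour there.

A thin command-line front end over the same functions is installed at
`inst/scripts/vesselpipe-cli.R` with subcommands `phantom`, `train`,
`segment`, `postprocess`, `eval` and `analyze`.

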