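---
title: "Segmenting HeLa cells in serial block-face EM: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting HeLa cells in serial block-face EM: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(helaseg)
```

## The problem

Serial block-face scanning electron microscopy (SBF-SEM) images a resin-
embedded sample as an aligned stack of 2D slices — thousands of cells at
roughly 10 × 10 nm pixels and 50 nm slice spacing. For HeLa cells imaged this
way, a recurring analysis task is four-class semantic segmentation of each
slice: *background* (bright, smooth resin), *cell* (darker, textured
cytoplasm), *nuclear envelope* (a thin dark membrane ring), and *nucleus*
(the large region the ring encloses, brighter than the envelope).

`helaseg` implements a complete desk-scale version of a comparison framework
for this task: a classical image-processing segmentation algorithm, a
patch-pair factory implementing several training strategies, a four-class
U-Net trained from scratch, class-wise morphological post-processing, and
per-slice accuracy/Jaccard evaluation. A synthetic phantom generator with
exact ground truth makes every stage testable without the (very large) public
EM volumes.

## The phantom generator

`phantom_spec()` / `generate_phantom()` emulate the appearance that drives
the segmentation problem, not the physics of the microscope:

* a **bright, smooth background** (default mean 200) that is strictly
  brighter than everything else;
* several **non-overlapping cells** of darker, mildly textured cytoplasm
  (mean 110) containing a few dark ellipsoids imitating mitochondria;
* per cell, a **star-convex nucleus** (mean 150) whose boundary is a random
  low-order Fourier perturbation of a circle — the `invagination_amplitude`
  parameter controls how deeply the boundary folds, mimicking nuclear
  invaginations;
* a **dark envelope ring** (mean 40) of constant width (default 5 px)
  obtained by dilating the nucleus mask, so the ring *exactly* separates
  nucleus from cytoplasm in the ground truth;
* a **spherical-cap z-profile**: each nucleus' radius shrinks toward its
  first and last slices (with a jittered z-centre per cell), reproducing the
  regime where per-slice segmentation is hardest — small, irregular nuclei
  near the top and bottom of a cell;
* **per-cell intensity offsets** (sd 8) on cytoplasm, envelope and nucleus:
  neighbouring cells in EM differ visibly in shading. This is the feature
  that makes "training on patches from many cells" genuinely different from
  "training on one cell"; without it the strategy comparison would be
  vacuous;
* additive Gaussian noise (sd 5 by default).

All randomness flows from the single `seed` in the spec, so identical specs
give identical volumes. Texture and mitochondria darkening are
mean-compensated within the cytoplasm: with noise, texture, mitochondria and
per-cell jitter all disabled, the four class means are recovered exactly from
the image through the ground-truth masks, which pins the rendering pipeline
in tests.

What the phantom does **not** model: charging/curtaining artifacts, organelle
diversity (Golgi, ER), partial-volume effects between slices, and
registration errors. Passing tests on phantoms therefore demonstrates that
the algorithms behave as designed under controlled conditions; they do not
certify accuracy numbers on real tissue.

## The image-processing algorithm

`segment_nucleus_volume()` runs, per slice:

1. **Gaussian low-pass** (`sigma = 2` px) — the standard Canny companion; the
   kernel is not specified by the original description, a Gaussian is used.
2. **Canny edges**: Sobel gradients, non-maximum suppression against the
   bilinearly interpolated magnitude along the gradient direction, hysteresis
   with the high threshold set automatically to the Otsu split of the
   gradient-magnitude distribution and the low threshold at 0.4 × high.
   Early sector-quantised suppression produced parallel double-edge lines
   that pinched thin slivers off the nucleus region; interpolated suppression
   gives single-pixel ridges.
3. **Superpixels** as 4-connected components of the edge complement; edges
   themselves carry label 0.
4. **Region selection**: regions smaller than `min_area` (500 px at a
   2000 px side, scaled with the slice area) or touching the image border are
   discarded; regions that vanish under a 3 px disk erosion are discarded as
   well — they are strips between parallel edge lines (most prominently the
   interior of the dark envelope band), not nucleus interior. On the central
   slice the surviving region containing the image centre (else the one with
   the most central centroid) is selected; on other slices every surviving
   region whose area lies mostly (> 50%) inside the neighbouring slice's mask
   is kept, which also collects disjoint fragments of an invaginated nucleus.
   The selection is dilated by 2 px (superpixels are the complement of drawn
   edge lines, hence eroded by about the line width), smoothed by a disk-5
   closing, and hole-filled.
5. **3D propagation** starts at the central slice and walks outward; an empty
   mask stops the walk, so slices beyond the nucleus' extent stay empty.

Two design points deserve emphasis because both were measured, not assumed.
First, the prior-overlap test is taken against the previous mask itself
(dilation radius 0 by default). Any positive dilation admits the thin band
regions hugging the nucleus — they are ~100% covered by a dilated prior — and
the mask then accretes one ring per slice; on a noise-free 512 px ROI this
is the difference between a volume Jaccard of ~0.2 and ~0.96. The dilation
remains available as an explicit tolerance for slice-to-slice misalignment.
Second, the envelope band of the automatic labels is grown *outward* from
the nucleus mask (`dilate(nucleus) \ nucleus`, width 5 px): the detected
nucleus boundary lies at the nucleus-side wall of the dark ring, so a band
centred on that boundary would systematically eat a nucleus rim.

Full frames are handled by `segment_background()` (Otsu on a heavily
smoothed slice, keeping the bright side, small holes absorbed),
`detect_cells()` (distance transform of the background complement, maxima
ranked by distance with minimum-separation suppression and row/column
tie-breaks), and `segment_cell_roi()` (automatic four-class labels for a
crop around one seed).

## Patch pairs and training strategies

Training pairs are aligned 128 × 128 image/label windows on a grid with 50%
overlap (stride 64); trailing windows that do not fit are dropped, so a
2000 px side yields 30 × 30 = 900 windows per slice. The five named
strategies differ in slice range (`"101:2:180"`, `"1:2:300"`,
`"230:10:370"` in the 1-based inclusive start:step:stop dialect), in
ground-truth source (manual vs automatic vs their union) and in ground-truth
variant (single-nucleus vs multi-nuclei; `single_nucleus_labels()` converts
one into the other). At full study scale the counts come out at 36,000 /
135,000 / 135,000 / 270,000 pairs; `strategy_pair_count()` reproduces this
arithmetic exactly, and `build_training_set()` executes the recipes at any
scale. Patch sets are lazy (a manifest plus volume references) so counting
never materialises pixel data.

## The U-Net

`build_unet()` constructs an encoder–decoder with four resolution levels
(three 2 × 2 max-poolings), two 3 × 3 same-padded convolutions + ReLU per
stage, channel widths doubling from `base_channels` (64 by default, so
64→128→256→512), dropout (0.5) after the deepest encoder stage and the
bridge, 2 × 2 transposed-convolution upsampling, skip concatenations, and a
1 × 1 four-way per-pixel classifier. Under the layer-counting convention in
which the input, every convolution, ReLU, dropout, pooling, transposed
convolution, concatenation, softmax and the pixel-classification stage each
count as one layer, the default network has exactly 46 layers
(`unet_layers()` enumerates them).

Training (`unet_train()`) is plain mini-batch softmax cross-entropy with
Adam; the default hyperparameters are 15 epochs, learning rate 1e-3 and
batch size 64, with everything overridable for desk-scale runs. There is no
validation split or early stopping: the epoch budget is fixed. All forward
and backward passes are dense-array computations routed through BLAS matrix
multiplication; the backward pass is verified against finite differences in
the test suite, which is the strongest correctness check such an
implementation admits. Weight initialisation, shuffling and dropout all
derive from the config seed, so a training run is bit-reproducible on one
machine.

`predict_slice()` handles slices of arbitrary size by tiled inference:
128 px tiles at stride 64 over a reflectively padded image, keeping each
tile's central 64 × 64 for the mosaic. Slices smaller than a tile take the
same path (padding up, cropping back). Class scores are converted to codes
by arg-max with ties broken toward the lower class code.

## Post-processing

`postprocess_labels()` cleans each class separately — hole filling, closing
with a 3 px disk, and removal of connected components smaller (strictly)
than 3200 px on a 2000 × 2000 slice; the threshold is anchored to 0.08% of
the slice area and scales with it. The background skips hole filling (its
holes are the cells). The envelope gets the repair step instead: nucleus and
cell are dilated and their overlap is added to the envelope, closing small
ring discontinuities. Aggregation applies the cleaned masks with precedence
nucleus > envelope > cell > background, and pixels claimed by no cleaned
mask keep their original class, so the output is always a total labelling.
The operation is idempotent on all test fixtures and modifies well under 1%
of pixels when 0.5% speckle is injected.

## Evaluation

`evaluate_volume()` computes per-slice confusion counts on the binary
nucleus mask — nucleus class versus everything else, with the envelope
excluded from the positive set by default since "nuclear area" is read as
the region the envelope encloses — then accuracy `(TP+TN)/(TP+TN+FP+FN)` and
Jaccard `TP/(TP+FP+FN)`. A slice with empty ground truth *and* empty
prediction has an undefined Jaccard: it is reported as `NA` and excluded
from range means (a 0 would be an arbitrary penalty on slices where nothing
was there to find); a slice with ground truth but an empty prediction scores
0. Range summaries are unweighted means of per-slice values over slice
ranges given in the same start:step:stop dialect.

## Problem sizes used in tests

The test suite and the acceptance script run entirely on phantoms at sizes
chosen to exercise every code path at interactive speeds: 256 px fixtures
for unit tests; a noise-free 512 px ROI with 40 slices for the
image-processing recovery and the central-versus-extreme slice profile; 200
pairs of 128 × 128 at base width 8 for the U-Net smoke training; and 512 px
frames with 6 cells, 64 px patches, 72 pairs and 12 epochs per model for the
many-cells-versus-one-cell comparison (three seeds, majority). Base width 8
rather than 64 keeps single-CPU training in minutes; depth, patch geometry
and the 46-layer structure are unchanged.

## Known limitations

* The image-processing algorithm targets the *central* nucleus of an ROI by
  construction; evaluated against multi-nuclei ground truth its Jaccard is
  bounded by the neighbour-nuclei mass, which is exactly the single-vs-multi
  ground-truth distinction the evaluation module exposes.
* The pure-R U-Net is practical at desk scale but not at the full
  270,000-pair study scale; the architecture and training loop are the same,
  the budget is not.
* Per-slice (2D) post-processing only; no 3D regularisation.
* The phantom's appearance model is deliberately minimal (see above), and
  instance identity of cells across slices is out of scope.
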