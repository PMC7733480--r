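---
title: "Detecting and segmenting intracranial aneurysms on CTA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and segmenting intracranial aneurysms on CTA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`aneuseg` implements an end-to-end pipeline for automatic detection and
voxel-wise segmentation of intracranial aneurysms on computed tomography
angiography (CTA): preprocessing with multi-scale Hessian vesselness
channels, a dual-pathway patch-based 3D convolutional network trained with
a soft Dice loss under k-fold cross-validation, STAPLE label fusion of the
fold sub-models, ensembling of three input-configuration variants, and a
volume-binned detection/segmentation evaluation harness. Because clinical
CTA cohorts of ruptured aneurysms are not publicly available, the package
ships a synthetic phantom generator so that every stage is exercised,
tested and reproducible on desk-scale hardware.

This vignette explains the model and the design decisions; the README shows
a worked example.

## The synthetic phantom generator

`phantom_spec()`/`generate_phantom()` emulate the gross radiological
appearance of a head CTA rather than its physics:

* **Vessels** are tubes of constant radius around cubic-spline-interpolated
  centerlines, rasterized by thresholding an exact distance-to-polyline
  field. This keeps the geometry analytically checkable (a tube's volume
  and surface are known).
* **Aneurysms** are ellipsoids attached tangent to the vessel wall. The sac
  penetrates the lumen by 20% of its attachment semi-axis, so vessel and
  sac fuse into one connected bright structure while the overlap stays
  around 3% of the sac volume (a spherical-cap bound). Ground truth is the
  sac minus the lumen, so reference volumes are well defined; the rasterized
  component volume stays within 15% of the requested mm^3 at the voxel
  sizes used here.
* **Intensities** are arbitrary HU-like values with the ordering that
  drives every downstream stage: parenchyma (40) < hemorrhage (65) <
  vessel = aneurysm (250) < skull (1000), all configurable. The skull is an
  ellipsoidal shell fitted to the grid extent, rendered before the soft
  tissue so that a sac grazing the shell keeps its own intensity; voxels
  outside the shell are air (0). No published intensity calibration exists
  for this task, and only the ordering matters to masking, normalization
  and vesselness.
* **Noise** is additive Gaussian (default sd 8), seeded; there is no beam
  hardening, motion, or contrast-bolus simulation. Spacing is anisotropic
  by default (0.62 x 0.62 x 1.0 mm) to mimic clinical slice thickness in
  the 0.62-1.25 mm range.

`make_cohort()` derives per-case seeds from a master seed, draws aneurysm
volumes uniformly from a configurable range (default 20-500 mm^3, matching
the scale of clinical volumes, tens to hundreds of mm^3), jitters the
attachment position, and gives a case a second, opposite-side aneurysm with
probability 0.2. A geometry draw that fails validation (two colliding sacs)
is redrawn deterministically from a derived seed, so cohorts are
reproducible bit-for-bit.

What passing tests on phantoms does *not* show: robustness to bone-adjacent
vessels with calcified plaque, venous structures, motion artifacts, or
anatomy-dependent failure modes. The phantoms establish that the machinery
is correct, not that clinical performance transfers.

## Preprocessing

The fixed chain is mask, enhance, resample, normalize; running it twice on
the same input is bit-identical.

* **Brain mask.** A surrogate for atlas-based brain extraction:
  keep voxels in the soft-tissue band (above an air threshold of 20, below
  a bone threshold of 500), take the largest 26-connected component, close
  it with a radius-2 ball, fill internal holes, and re-take the largest
  component. The contract that matters downstream is that the skull shell
  is excluded and intracranial vessels are included; on phantoms the mask
  excludes over 99% of skull voxels and retains over 95% of vessel voxels.
* **Vesselness.** A Frangi-type bright-on-dark filter: at each of 5
  log-spaced scales (sigma in voxel units of the native grid) the volume is
  Gaussian-smoothed, the scale-normalized Hessian eigenvalues
  |l1| <= |l2| <= |l3| are computed per voxel, and the response combines the
  plate term R_A = |l2|/|l3|, the blob term R_B = |l1|/sqrt(|l2 l3|) and the
  Frobenius structureness S with weights alpha = beta = 0.5; voxels whose
  two largest-magnitude eigenvalues are not both negative are zeroed. Two
  configured instances (scales 0.5-5 and 5-15 voxels) give a small-vessel
  and a large-structure channel. The structureness weight `c = "auto"` is
  half of the *maximum Frobenius norm over the whole scale sweep*, not per
  scale: a per-scale normalization would make the response scale-free and
  the maximizing scale meaningless, while a global c keeps per-scale
  responses comparable (the maximal response on a radius-2 voxel cylinder
  then occurs near sigma = 2, as the Gaussian-tube closed form predicts)
  and still cancels affine intensity rescaling.
* **Resampling** to 0.5 mm isotropic: trilinear for images, nearest
  neighbour for masks, output grid co-centered with the input so world
  extent is preserved within a voxel. Vesselness is computed *before*
  resampling because its scales are quoted in native voxels; the choice is
  recorded in the stack's parameters.
* **Normalization.** The CTA channel is mapped linearly so the 5th/95th
  intensity percentiles inside the brain mask become 0/1, then clipped —
  percentile normalization implies saturated outliers, and unbounded tails
  would destabilize training. Vesselness channels are z-scored (population
  sd) over the brain mask.

`build_stack()` assembles the variant inputs: `Orig` and `LDim` use the
single normalized CTA channel; `Vess` uses CTA plus the two vesselness
channels.

## The dual-pathway segmentation network

The architecture follows the dual-resolution patch-network family for 3D
lesion segmentation: 11 layers; two identical pathways of eight 3x3x3
valid convolutions (batch normalization, parametric ReLU), with residual
connections entering layers 4, 6 and 8; layers 9 and 10 are "fully
connected" 1x1x1 convolutions on the concatenated pathway features with a
residual spanning the block (layer 10); layer 11 is the two-class softmax
classifier. This is the one layer accounting that reconciles "11 layers",
"residuals at 4, 6, 8, 10" and "9 and 10 fully connected" within that
family. The output window is `segment - 16` per axis (eight valid 3^3
convolutions); a 25^3 segment yields 9^3 predictions per pass, asserted at
build time.

The second pathway sees the same world location in a volume average-pooled
by a factor of 3; its output is upsampled by repetition and cropped using
the exact alignment offset between the two grids (carried per patch, and
mirrored when a patch is flipped). Because pooling is anchored at the
volume origin and the crop uses global alignment, dense inference is fully
convolutional: tiling a volume into output windows gives bit-identical
results to a single whole-volume pass, which the tests assert.

Training samples segments 50/50 from foreground and in-mask background
centers (the standard remedy for extreme class imbalance here: foreground
is well under 1% of voxels), flips each patch independently along the three
axes with probability 0.5, and minimizes the soft Dice loss
`1 - (2*sum(p*t) + s) / (sum(p) + sum(t) + s)` with smoothing `s = 1`.
The forward and backward passes are implemented in R on im2col matrices so
the heavy lifting is BLAS matrix multiplication; the analytic gradients of
every parameter class (conv, batch norm, PReLU, residual, upsampling,
classifier) are verified against numerical differentiation in the tests.

Settings fixed by the studied design: batch size 15, 30 epochs, batch
normalization, PReLU, Dice loss, segment 25^3 (Orig/Vess) or 45^3 (LDim),
1 or 3 input channels, downsampling factor 3. Settings the studied design
leaves open, exposed in `network_config()` with recorded defaults: the
optimizer (Adam, lr 3e-3, beta 0.9/0.999), feature widths (default
4,4,4,4,8,8,8,8 with 16 1x1x1 features — a reduced profile sized so CPU
tests finish in minutes; literature-scale widths are a config change), the
number of batches per epoch, and the 50/50 sampling ratio. Batch
normalization keeps running statistics (momentum 0.9) so inference is
deterministic and independent of tile batching.

## Cross-validation, STAPLE fusion and the ensemble

`make_folds()` partitions cases (patients) into k validation folds of
near-equal size (k = 5 at full fidelity, an 80/20 split; smoke
configurations may lower k to 2, which is exposed in `pipeline_config()`).
Each fold's model predicts every test case; the k binary outputs per case
are fused with STAPLE.

`staple()` is binary expectation-maximization over the latent true
segmentation: the E-step computes the per-voxel foreground posterior from
the current rater sensitivities p_j, specificities q_j and a foreground
prior (by default the mean foreground fraction of the inputs); the M-step
re-estimates p_j and q_j against the posterior. Initialization p_j = q_j =
0.99, tolerance 1e-6 on the posterior, at most 100 iterations —
literature-standard values. Voxels are grouped by their rater-decision
pattern (at most 2^J patterns for J raters), which makes the EM exact and
fast; tests verify agreement with a naive per-voxel EM to 1e-6, parameter
recovery on simulated raters, and per-iteration monotonicity of the
log-likelihood. All-empty inputs return an empty consensus flagged
degenerate rather than an error, since an empty prediction is a legitimate
model output.

The three variant outputs (Orig, Vess, LDim) are combined with the same
mechanism — STAPLE over three binary masks, consensus thresholded at 0.5,
which degenerates to a 2-of-3 majority for symmetric rater estimates. The
original ensembling rule is not fully specified in the source design (it
could equally have averaged continuous confidences); the package treats
STAPLE-over-binary as the default for consistency with fold fusion and
offers `method = "majority"` as the explicit fallback. Fusion operates on
binary masks because STAPLE is defined over discrete rater decisions.

## Evaluation

Detection operates on connected components (26-connectivity by default,
6 switchable): a reference component is detected if at least one predicted
voxel overlaps it (a minimum-overlap-fraction switch tightens this); each
predicted component is assigned to the reference component with which it
shares most voxels; unassigned predicted components are false positives;
several predicted components on one reference merge into a single true
positive, whose pair Dice uses the union of the assigned components. The
matching rule is the most permissive consistent reading of component-level
counting and is verified against an exhaustive set-intersection oracle on
randomized grids.

Metrics follow the standard formulas — sensitivity TP/(TP+FN)*100,
precision TP/(TP+FP)*100, F1 = 2SP/(S+P)/100 computed from *unrounded*
percentages, FPs/scan = FP/n_scans, Dice 2|A∩B|/(|A|+|B|), Pearson r over
matched component volumes. Reporting rounds percentages half away from
zero to integers and DSC/F1/FPs-per-scan to two decimals, reproducing the
published tables from their printed counts. Volume-binned reports restrict
reference components (TP/FN) by reference volume and false positives by
the predicted component's own volume — the reading under which the
published binned FP counts decrease with the threshold; the rule is a
documented choice, not a claim about the original system. Empty strata are
absent from the report rather than zero-filled.

## Numerical choices and degenerate inputs

* Percentile/z-score normalization of a constant region returns zeros with
  a warning instead of dividing by zero.
* `binarize()` uses `>= threshold`, so a threshold of 1.0 keeps only exact
  ones.
* The vesselness filter rejects scale ranges whose 3-sigma support exceeds
  half the smallest grid extent; the full-fidelity 5-15 voxel range
  therefore requires clinically sized grids, and desk-scale smoke
  configurations use reduced ranges via `pipeline_config(scale_ranges=)`.
* STAPLE clamps p and q to [1e-7, 1-1e-7] to keep the E-step finite under
  perfect agreement.
* Ties in component assignment (equal overlap) go to the lowest reference
  id; rounding is half away from zero, matching the printed tables.
* Seeds: every stochastic step (phantom noise, cohort draws, fold split,
  weight init, patch sampling, flips) flows from explicit integer seeds;
  identical configs reproduce identical artifacts bit-for-bit.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on synthetic
phantoms at reduced scale, chosen so that a laptop CPU reproduces them in
minutes: preprocessing and filter properties on 40^3-48^3 grids; network
learnability by overfitting a single high-contrast 250 mm^3 phantom for 30
epochs (training Dice above 0.5); and an end-to-end smoke cohort of 6
training plus 2 test phantoms, 2 folds, all three variants, fusion,
ensembling and binned evaluation. The full-fidelity configuration (k = 5,
segment 45^3 for LDim, literature-scale widths, hundreds of epochs of
batches) is the same code path with different `pipeline_config()` numbers.

## Known limitations

* The phantom's intensity model is piecewise-constant plus Gaussian noise;
  vesselness on real CTA faces smoother gradients and more confounders.
* The reduced-width network is a learnability and correctness vehicle; no
  claim is made that its clinical accuracy matches GPU-scale training.
* Brain masking is intensity-and-morphology only; it would under-perform
  on real scans with open skull defects or heavy beam hardening.
* Multi-class STAPLE, soft (probabilistic) fusion and learned vote weights
  are out of scope; the ensemble is three binary raters.
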