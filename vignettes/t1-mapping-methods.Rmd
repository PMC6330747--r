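---
title: "Automated myocardial native T1 mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated myocardial native T1 mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiot1)
```

## The problem

Native myocardial T1 is a quantitative tissue parameter sensitive to diffuse
interstitial fibrosis. Free-breathing slice-interleaved acquisitions produce,
per short-axis slice, eleven T1-weighted magnitude images at inversion times

```{r}
make_ti_schedule(1000)
```

(`Inf` denotes the fully recovered image; the trains starting at 115 ms and
350 ms are incremented by the cardiac cycle duration RR). Reconstructing a T1
map requires (i) knowing where the myocardium is in each image, (ii) aligning
the eleven images despite residual respiratory motion, and (iii) fitting a
relaxation model per pixel. `cardiot1` automates all three: a fully
convolutional network segments each image, morphological quality control
accepts or repairs the masks, and resampling the segmented ring onto a polar
grid aligns the images *implicitly* — no registration step — before
pixel-wise fitting.

## Signal model

Each pixel follows magnitude inversion recovery with perfect inversion,

$$S(TI) = A\,\lvert 1 - 2 e^{-TI/T_1}\rvert,$$

a two-parameter model in the amplitude $A$ and relaxation time $T_1$. The
acquisition literature for this sequence specifies "a 2-parameter model"
without printing the equation; the perfect-inversion magnitude form is the
standard reading and is isolated in the single function `ir_signal()`, so an
inversion-efficiency factor other than 2 would be a one-line change. The
fully recovered sample enters the fit analytically as $S(\infty) = A$, never
as a large float pushed through `exp()` (although IEEE arithmetic would in
fact return exactly 0 for `exp(-Inf)`).

For fixed $T_1$ the model is linear in $A$, so the least-squares amplitude
has the closed form $\hat A = \sum_k y_k f_k / \sum_k f_k^2$ with
$f_k = \lvert 1 - 2 e^{-TI_k/T_1}\rvert$. `fit_pixel()` therefore profiles
the problem to one dimension: an 80-point log-spaced grid over
$T_1 \in [100, 3000]$ ms brackets every local minimum the magnitude model's
null points can create, and golden-section refinement polishes the best
bracket. This is deterministic, derivative-free, and immune to the null-point
local minima that defeat naive descent initialized on the wrong side of the
signal null. Noiseless self-consistency is sub-0.5 ms; under noise the
profiled fit matches an exhaustive two-dimensional grid search to within
1 ms mean absolute error (both are recomputed by `scripts/acceptance.R`).

## The synthetic phantom

Patient data cannot ship with a package, so every stage is exercised on a
phantom with exact ground truth (`phantom_config()`, `render_stack()`): an
annular myocardium (default T1 1100 ms) around a circular blood pool
(1700 ms) on a dark background, rendered at the eleven TIs on a 2.1 mm grid.
Two aspects matter for realism:

* **Equilibrium contrast.** Tissues differ not only in T1 but in equilibrium
  signal (proton density, inflow): blood is brighter than myocardium
  (`pd_blood = 1.6`) and the air background nearly dark
  (`pd_background = 0.1`). Without this the fully recovered image would be
  featureless — every tissue recovers to the same $A$ — and no segmenter
  could learn from it; with it, the infinite-TI image has the highest
  myocardium-to-blood contrast in the stack, which is also why that image
  anchors the refinement step.
* **Motion.** Respiratory motion at this stage is predominantly in-plane
  translation; the phantom draws one integer shift per TI (uniform within
  `motion_amplitude`) and re-renders the geometry at the shifted center, so
  translation is exact and the truth masks stay binary.

Noise is Gaussian on the magnitude signal by default (adequate at phantom
SNR); a Rician option (`noise_model = "rician"`) applies Gaussian noise on
two quadrature channels before the magnitude. Elliptical and broken-ring
(`c_shape`) variants generate the improper geometries the QC gate must
reject. The phantom deliberately omits torso anatomy, through-plane motion,
k-space/parallel-imaging artifacts and partial-volume fuzz at tissue borders
beyond what pixel sampling creates; passing tests therefore demonstrate the
*mechanics* of the pipeline, not clinical segmentation difficulty.

## Segmentation network

`build_network()` constructs a U-Net-style encoder–decoder operating on
mean-0/SD-1 normalized images (`normalize_intensity()`). Each bottleneck is
batch-normalization → ReLU → 3×3 convolution, with dropout inside every
bottleneck; down-steps are 2×2 max-pools that double the kernel count,
up-steps nearest-neighbor upsamplings that halve it, and skip connections
concatenate encoder channels into the decoder. A final 1×1 convolution emits
two class maps through a softmax; segmentation is the per-pixel argmax, with
the exact tie resolved to background. One deviation from a pure
pre-activation stack: the input stem is a plain convolution, because a
BN → ReLU prefix acting directly on the 1-channel normalized image would
clip every sub-mean intensity before any kernel sees it.

Everything is implemented directly on R arrays in a channel-last `[H, W, N,
C]` layout — convolution as an im2col gather plus one BLAS matrix product per
layer, with hand-derived gradients (verified against central differences to
4 significant digits). Training minimizes pixel-wise cross-entropy with Adam
(learning rate 0.001, weight decay 0.001 on convolution weights) under
geometric augmentation: random translation, mirroring and elastic
deformation applied with probabilities 0.95, 0.95 and 0.5, the identical
transform applied to image and label, labels re-binarized, and no intensity
transform. Translations are whole-pixel (uniform within ±5 px), so the label
warp is exact and thin rings are not eroded by re-binarization; the elastic
field is Gaussian-smoothed white noise (smoothness 8 px, amplitude 2 px —
chosen so deformed annuli, including the thinnest walls the phantom
generates, stay annular; the parameters are exposed in `augment()`).

Two presets ship. `"tiny"` (depth 3, 10 base kernels, 64 px input, dropout
0.2) trains on one CPU in a few minutes and is ample for phantom geometry;
its smoke test — 200 phantom pairs, 300 iterations, batch 6 — must strictly
decrease the loss and reach held-out Dice ≥ 0.90. `"full_scale"` (depth 5,
34 base kernels, 256 px input, dropout 0.5) has ≈ 8.9 million parameters,
matching the ~9 million of a full-scale clinical network; it is constructed
and counted in tests but not trained there. Training pairs for the smoke
test use the infinite-TI phantom image: it is the stable high-contrast
member of the stack, and pipeline-level tests decouple from network quality
entirely by using the ground-truth segmenter stub (`segmenter_truth()`), so
the smoke test's scope is optimization health, not clinical transfer.
Batch-norm running statistics (momentum 0.1) are frozen at inference, and
inference is deterministic.

## Shape quality control and refinement

A plausible short-axis myocardium is a single ring: Euler number 0 (one
component, one hole) and moment-ellipse eccentricity ≤ 0.65 (the maximum
observed across manually segmented myocardia). `area_filter()` first removes
8-connected components below 5 cm² (strict inequality, physical area = pixel
count × spacing²; spacing defaults to 2.1 mm) and keeps the largest
survivor. `euler_number()` uses the exact 2×2 quad-count formula for
8-connected foreground / 4-connected background, which keeps thin annuli
hole-preserving; `eccentricity()` uses the standard normalized
second-central-moment ellipse. The eccentricity is computed on the annulus
as segmented, not its filled hull — the moment ellipse of a ring tracks its
epicardial outline, which is the elongation that matters.

An improper mask is repaired by affinely registering the infinite-TI mask of
the same slice onto it (`refine()`): translation seeded at the centroid
offset, then a coarse grid over rotation ±15° (step 3°) and scale 0.9–1.1
(step 0.05) with local translation tweaks, then hill-climbing with halved
steps; the objective is Dice, the identity is always a candidate (so
refinement never does worse than the untransformed reference), and the
search runs on a cropped region around the masks for speed. The bounds cover
realistic respiratory displacement at 2.1 mm spacing. If the infinite-TI
mask is itself improper, no refinement is attempted and the image is
excluded. A segmentation counts as successful if a proper mask results,
refined or not — the single predicate (`segmentation_successful()`) the
slice gate counts.

## Polar resampling as implicit motion correction

`to_polar()` resamples each image's segmented ring onto a 20 × 360 grid: 360
rays at 1° from the mask's own center of mass, and on each ray 20 samples
uniformly spaced from the endocardial to the epicardial crossing (endpoints
included), bilinearly interpolated. 20 samples exceed the maximum expected
wall thickness (15 px), so the transform loses no data. Because every image
is resampled about *its own* mask centroid, a global translation of the
heart moves the origin with it and the polar image is unchanged — this is
the implicit correction of translational motion, quantified in the
acceptance suite as < 1% RMS discrepancy between polar images of stacks
differing by ≤ 5 px shifts. Per-ray normalization from endo to epi
additionally provides a non-rigid radial alignment across TIs.

Conventions chosen where the method leaves them open: angles measured
counter-clockwise from the +x image axis; multiple wall crossings on a ray
(papillary tissue, broken rings) resolve to the innermost contiguous run —
the myocardium is the ring nearest the cavity; rays that never cross the
mask are flagged invalid and excluded from fitting, and a slice with more
than 90 invalid rays of 360 is marked unreliable in the QC report. Radial
sampling includes both endpoints (`m = 0` at endo, `m = C-1` at epi),
isolated in one function should a cell-centered convention be preferred.

`reconstruct_map()` fits every polar cell over the TIs whose image passed QC
and whose ray is valid. The slice-level rule — at least 8 successfully
segmented images, else the slice is rejected (a distinct condition class,
not a per-cell NA) — is also applied per cell as a conservative extension:
a cell with fewer than 8 valid observations is marked invalid.
`from_polar()` maps the fitted polar map back onto the Cartesian grid of the
shortest-finite-TI mask by bilinear interpolation in (normalized radius,
angle), with angular wrap across the 359°→0° seam.

## Pruning and summary statistics

Manual analysis excludes sub-endocardial and sub-epicardial border pixels;
`prune_mask()` mimics this by skeletonizing the ring (Zhang–Suen thinning to
the 1-px central contour) and dilating with a disc so the retained band's
full width is one-third of the mean wall thickness (`mean_wall_thickness()`,
the mean over valid rays of epi − endo radius). The one-third is
conventional rather than principled and is exposed as `prune_fraction`; the
reading of "one-third" as the band's full width (dilation radius ≈ width/2)
rather than the dilation radius itself is the stricter of the two plausible
readings and is configurable. Walls of 3 px or thinner keep just the
skeleton; a disconnected skeleton falls back to its largest fragment with a
warning.

`summarize_t1()` averages T1 over the pruned mask per slice (regional) and
over all slices (global), excluding pixels outside the physiological
acceptance window for native myocardium at 1.5 T, 850–1500 ms, endpoints
inclusive. A slice whose pixels are all excluded yields NA with a warning
and does not disturb the others.

Agreement statistics follow the conventions of method-comparison studies in
this field: Dice overlap (`dice()`, two empty masks score 1), Bland–Altman
bias with ±2 SD limits of agreement (2, not 1.96 — `bland_altman()`),
Pearson r alongside the zero-intercept regression slope
$\sum xy / \sum x^2$ (`corr_with_origin_slope()`), and ICC(2,1) — two-way
random effects, absolute agreement, single measure — with the F-based 95%
interval (`icc()`); the ICC variant is the standard choice for two raters
measuring the same physical quantity, and the implementation is verified
against an independent reference implementation on a frozen fixture.

## Numerical choices and problem sizes

* T1 search range [100, 3000] ms; convergence requires the optimum strictly
  inside it. All-zero signals return a non-converged fit.
* Bilinear interpolation everywhere (polar sampling, inverse transform, mask
  warping); masks re-thresholded at 0.5 after interpolation.
* Acceptance-range endpoints inclusive; area-filter threshold strict.
* Test and acceptance runs use 64–160 px grids, 96 px end-to-end phantoms,
  200 training pairs × 300 iterations, and 500-replicate noise studies —
  sizes at which every check completes comfortably on one CPU while leaving
  the numerical claims (sub-ms fits, <1% alignment error, <2% round trip)
  unchanged from larger grids.
* Determinism: phantom rendering, network initialization, batching,
  augmentation and dropout all derive from explicit seeds; reruns are
  byte-identical.

## Known limitations

The phantom's simplicity means segmentation quality numbers here say nothing
about clinical images; the network module is a faithful, trainable
implementation, but transfer to patient data would require real training
pairs (a weights-import hook, `load_weights()`, accepts externally trained
parameters). DICOM input is not parsed — NIfTI with a JSON inversion-time
sidecar is the supported interchange format, and masks travel as PNG.
Three-parameter or Look-Locker-corrected fitting and post-contrast/ECV
mapping are out of scope.
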