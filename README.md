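# cardiot1

Automated analysis of myocardial native T1 mapping acquisitions in R.

Free-breathing slice-interleaved T1 mapping yields, per short-axis slice,
eleven T1-weighted magnitude images at inversion times
`TI = Inf, 115, 115+RR, ..., 115+4RR, 350, 350+RR, ..., 350+4RR` ms
(RR = cardiac cycle duration). Turning those into a myocardial T1 map
normally requires manual contouring and explicit motion correction.
`cardiot1` automates the whole chain for researchers working with such
acquisitions:

1. **Segmentation** — a U-Net-style fully convolutional network
   (batch-norm → ReLU → 3×3 convolution bottlenecks, dropout, max-pool /
   nearest-upsample with skip connections, two-channel softmax head),
   implemented natively on R arrays with hand-derived gradients and Adam.
2. **Shape quality control** — 5 cm² area filter, Euler number (= 0 for an
   annulus) and moment-ellipse eccentricity (≤ 0.65); improper masks are
   repaired by affine registration of the reliable infinite-TI mask
   (translation, rotation, scaling, Dice objective) or excluded.
3. **Implicit motion alignment** — each image's segmented ring is resampled
   onto a 20 × 360 polar grid about its own mask centroid (360 rays at 1°,
   20 samples endo→epi per ray); translation of the heart moves the origin
   with it, so no registration step is needed.
4. **Pixel-wise fitting** — magnitude inversion recovery
   `S(TI) = A·|1 − 2·exp(−TI/T1)|`, profiled to a 1-D search over T1 (closed
   form for A), fitted per polar cell over the TIs that passed QC; slices
   with fewer than 8 usable images are rejected.
5. **Pruning and statistics** — the fitted map is inverse-transformed onto
   the shortest-TI mask, a mid-wall band (skeleton dilated to one-third of
   mean wall thickness) excludes partial-volume borders, and global/regional
   T1 means are taken over the 850–1500 ms native-T1 acceptance window.
6. **Method agreement** — Dice, Bland–Altman (bias ± 2 SD), Pearson r with
   zero-intercept slope, and ICC(2,1) with 95% CI.

A synthetic cardiac phantom (`phantom_config()` / `render_stack()`) with
exact ground-truth geometry, T1 field and motion trace makes every stage
testable without patient data.

## Worked example

```r
library(cardiot1)

# a noiseless 5-px-motion phantom "patient" slice with known T1 = 1100 ms
cfg <- phantom_config(grid_size = 96, r_endo = 14, r_epi = 22,
                      motion_amplitude = 5, seed = 51)
st  <- render_stack(cfg)

# run the pipeline with the ground-truth segmenter stub
res <- run_patient(list(st), segmenter_truth(st$truth$masks), run_config())
res$summary
#> t1_summary: global T1 = 1100.0 ms over 1 slices (416 px used, 0 excluded)
#>   slice 1: 1100.0 ms (n=416)
```

Despite per-image translations of up to 5 px, the polar transform aligns the
stack and the global T1 lands on the ground truth (1100 ms) to well under a
millisecond — the motion never enters the fit. With a trained network
instead of the stub, replace the segmenter:

```r
pairs <- lapply(1:200, function(s) {
  p <- phantom_config(grid_size = 64, r_endo = sample(8:12, 1),
                      r_epi = sample(14:18, 1), noise_sd = 0.05, seed = s)
  stk <- render_stack(p)
  list(image = normalize_intensity(stk$images[, , 1]),
       label = stk$truth$masks[[1]])
})
net <- train(pairs, network_config("tiny", iterations = 300, seed = 7))
mask <- segment(normalize_intensity(st$images[, , 1]), net)
```

A command-line front end wrapping these functions is installed at
`exec/cardiot1` (subcommands `phantom`, `train`, `segment`, `map`, `run`,
`eval`); inputs are NIfTI stacks with a JSON inversion-time sidecar, masks
are PNG, T1 maps are written as NIfTI in ms.

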