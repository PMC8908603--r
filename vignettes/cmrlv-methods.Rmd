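---
title: "Automated LV volumetry: models, conventions and numerical choices"
author: "cmrlv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated LV volumetry: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrlv)
```

This vignette is the package's own account of its methods: the geometric
and statistical models it implements, the conventions it fixes where the
underlying methodology leaves choices open, what the synthetic phantom does
and does not emulate, and the numerical decisions that matter for
reproducibility.

## 1. Plane geometry and spatial normalisation

All geometry uses the DICOM patient (LPS) convention: an `image_plane`
carries the patient-space position of the *centre* of pixel (0, 0), unit
direction vectors for increasing row and column index, pixel spacings in
mm, and a slab thickness equal to the inter-slice spacing of the stack it
belongs to. Pixel indices are 0-based and may be fractional. The plane
normal is `row_dir x col_dir`.

Spatial normalisation maps a study into a canonical reference frame so a
segmentation network always sees the heart at the same position, scale and
orientation. The transform is fixed by three conditions:

* the common point of the mid short-axis slice, the 2-chamber plane and
  the 4-chamber plane maps to the origin (solving the 3x3 system
  `n_i . x = n_i . o_i`);
* the SAx/2Ch intersection direction maps onto the y-axis, so the outflow
  tract is consistently oriented;
* the SAx normal maps onto the z-axis, and in-plane resampling uses 1 mm
  pixels.

Two conventions had to be fixed where the construction is ambiguous:

* **Which SAx slice anchors the centering.** Any slice gives a point on
  the same line (the long axis); we use the mid-stack slice, index
  `floor(n/2)`, as the representative.
* **The sign of the z-axis.** Both SAx normal orientations give a valid
  frame. We resolve it so a known apical point maps to negative z. The
  blood-pool centroid is *not* a reliable sign reference: for a realistic
  truncated-ellipsoid ventricle it lies within ~0.3 mm of the mid-stack
  anchor plane, so its sign would flip under tiny perturbations. The
  pipeline instead uses the centre of the apex-most slice (assuming
  apex-to-base stack ordering, the standard acquisition convention), which
  sits half a ventricle length away from the anchor and is numerically
  robust. `build_normalization()` accepts either form of reference.

Resampling is strictly in-plane (slices are never interpolated through
plane): each slice is regridded on axes that project the canonical x/y (or
the two canonical axes most orthogonal to the slice normal, for long-axis
views) onto the plane. Grayscale uses bilinear interpolation, label masks
nearest-neighbour so no new labels are invented. Degeneracy tolerances
(parallel planes, collinear points, singular normal matrices) are 1e-6
throughout and exposed as arguments. One numerical detail worth recording:
the output grid size is `floor(extent/spacing + 0.5 + 1e-9) + 1` — the
1e-9 slack keeps the grid stable when the extent sits exactly on a
half-pixel boundary, which otherwise makes results sensitive to last-bit
changes in the input geometry (e.g. after writing a study to JSON and
reading it back).

## 2. Mitral annulus landmarks and the valve plane

The basal extent of the ventricle cannot be decided from short-axis slices
alone, so the two mitral annular points in each long-axis view are
detected and a plane is fitted through them. The landmark representation
is a Gaussian-weighted distance map on the view's pixel grid,

$$ v(p) = \exp\left(-\frac{d(p)^2}{2\sigma^2}\right), $$

with `d` the in-plane distance in mm to the landmark; this is the target a
landmark-regression U-net predicts, and it is more robust than regressing
coordinates directly. `sigma` defaults to 5 mm — wide enough that the peak
survives blurring by a network, narrow enough that the two annulus points
(typically > 25 mm apart) do not interact; it is configurable.

Decoding is not uniquely defined by the encoding; the package uses argmax
followed by an intensity-weighted centroid over a window of half-width
`ceiling(sigma)` pixels, with ties broken at the lowest (row, column)
index. The refinement reaches well under half a pixel of error
(worst case ~0.26 px over 500 random sub-pixel landmarks at 1.5 mm
pixels). When a landmark sits exactly halfway between two pixels the
argmax choice — and hence the sign of the residual sub-pixel error — can
flip under last-bit perturbations of the geometry; the decoded point stays
within tolerance either way, and on bit-identical input the result is
bit-identical.

The valve plane is fitted to the four points (two per view) by total least
squares: the plane through the centroid whose normal is the smallest right
singular vector of the centred point matrix. Ordinary z-regression would
depend on the coordinate frame; orthogonal regression is
rotation-invariant, which the tests verify directly. The normal is
oriented so the ventricular side is positive, using an apical reference
point. With four points the fit is overdetermined by one, and the RMS
residual is reported as a quality signal: a large residual means the 2Ch
and 4Ch views disagree about where the annulus is, the signature of a
breath-hold shift between acquisitions. The plane is fitted per phase when
per-phase landmarks exist (the phantom provides them); otherwise the
ED-phase plane is reused, and ES volumes are trimmed with whichever plane
is available for that phase.

## 3. Volumetry

Volumes are computed by slab summation: each slice contributes
`pixel_area x slab_thickness` per labelled pixel, with the slab extending
half the inter-slice spacing to either side so slabs tile the covered
range contiguously (gaps included — anything else double-counts or leaves
holes). Stacks are validated to be parallel within 1e-3 rad and uniformly
spaced within 1%.

Basal trimming clips each pixel's slab column against the valve plane and
keeps the fraction on the ventricular side, clamped to [0, 1]:
with `d0` the signed distance of the pixel centre and `g` the dot product
of the valve normal with the slice normal, the kept fraction is
`0.5 + d0/(t |g|)`. Whole-slice inclusion/exclusion was rejected because
it cannot converge to the analytic truncated volume; fractional clipping
matches a Monte-Carlo sub-voxel clipping oracle within ~0.1% and makes the
measured EDV converge to the closed form. End-diastole is the phase with
the largest blood volume, end-systole the smallest (ties broken at the
lowest index). Myocardial mass uses the ED myocardium only, at the
standard CMR density of 1.05 g/ml (configurable).

Automated plausibility flags stand in for visual review, firing when a
defect reaches 5% of the cardiac volume (configurable): secondary
blood-pool components, slice-to-slice area jumps, detached myocardium, and
high valve-plane residuals. When a slice has multiple blood components the
trusted one is the component supported by the adjacent slices' blood
pools; attributing the defect to "everything but the largest component"
fails whenever an artifact is larger than the true pool on its slice.

## 4. The synthetic phantom

The phantom is a truncated ellipsoid: a blood pool with semi-axes
(a, b, c), cut by the valve plane at height `f x c` along the long axis
(default f = 0.6), wrapped in a uniform myocardial shell. Blood and shell
continue above the valve plane into an "atrium", mirroring the convention
of fully annotating basal and atrial slices and letting the valve-plane
correction decide inclusion — this is what makes trimming testable.
Contraction scales the blood pool isotropically with the cut plane
scaling along, so every phase has a closed-form volume
`V(s) = s^3 V_ED` and the ejection fraction hits its target exactly
(`s_ES = (1 - EF)^{1/3}`); the scale follows a `sin^2` profile over the
cycle, putting ES exactly at mid-cycle for an even phase count. The shell
thickness at each phase is solved by `uniroot` so the myocardial volume is
conserved (incompressible myocardium).

Defaults emulate a typical clinical prescription: 30 phases, 13 SAx slices
at 8 mm spacing and 1.5 mm pixels, 60% ejection fraction, ~117 ml EDV. The
stack starts a quarter-slice below the *epicardial* apex (the shell
extends a wall thickness below the blood pool — starting at the blood-pool
apex leaves shell uncovered and biases mass) and must reach at least one
slice above the valve plane. Grayscale is a three-level painting (blood
1.0, myocardium 0.5, background 0.1) with additive Gaussian noise, clipped
to [0, 1]; this is deliberately simple — the phantom tests geometry and
statistics, not image realism.

What the phantom does **not** emulate: MR physics (no bSSFP banding, coil
shading or partial-volume blur), papillary muscles and trabeculae (the
blood-pool convention makes them part of the pool anyway), pathology,
the right ventricle, or motion between phases. Passing tests therefore
demonstrate correctness of the geometry, trimming, metric derivation and
statistics — not clinical segmentation performance on real images.

`rescan()` models scan-rescan variability as a re-prescription of the
imaging planes: a random rigid move of all planes about the ventricle
(magnitudes up to the stated maxima) plus a through-plane shift of the SAx
stack, with the anatomy untouched — so analytic truth volumes are
unchanged and any measured difference is attributable to the measurement.
`breathhold_offset()` translates the long-axis plane *headers* while
keeping pixel content and pixel-space annotations fixed: every decoded
landmark then maps to a patient position shifted by the offset, and an
offset along the long axis biases EDV by exactly the closed-form
difference of the two truncated caps — the canonical basal mis-trimming
failure mode.

## 5. Segmentation stage

Segmentation is pluggable behind the signature
`segmenter(plane, phase, image)`. The oracle segmenter rasterises the
phantom's analytic anatomy on any requested grid, decoupling every
downstream stage from network quality; the pipeline detects it and skips
grayscale interpolation entirely (the oracle never reads pixels). The
blood pool is segmented in every phase; myocardium labels are kept only at
ED, which is identified from the untrimmed blood-volume curve *before* the
myocardium is needed — resolving the apparent circularity of
"diastole-only" myocardium segmentation.

The trainable U-net is implemented directly on BLAS matrix products
(im2col convolutions): encoder blocks of two 3x3 conv + batch norm + ReLU
stages with 2x2 max pooling, a bottleneck chain of dilated (Atrous)
convolutions, nearest-neighbour upsampling with skip concatenation, and a
1x1 softmax head; He initialisation, pixel-wise cross-entropy, Adam
(learning rate 1e-4, no decay, by default), and identical
scale/rotate/translate augmentation applied to image (bilinear) and mask
(nearest). Backpropagation is verified against finite differences in the
test suite (conv biases feeding batch norm are absorbed by the
normalisation; their gradient is exactly zero). Training is deterministic
given the config seed.

The toy-scale experiment trains a depth-2, 8-filter net on 64x64 ED-phase
slices from 17 varied phantoms (200 slices, 8 epochs, batch 8, learning
rate 1e-3 — a few hundred Adam steps, a schedule that converges reliably
across anatomy draws on a single CPU) and reaches a pooled foreground Dice
around 0.95 on 50 held-out slices from unseen phantoms. This validates the architecture and training
loop; clinical-grade segmentation is explicitly out of scope.

## 6. Precision statistics

For paired measurements (scan/rescan or read/re-read), the within-subject
standard deviation is computed by the root-mean-squared method,
`SEM = sqrt(sum(d_i^2) / 2n)`, and the CoV divides by the grand mean of
all 2n values (a per-pair-means denominator is available for sensitivity
analysis; they coincide for balanced pairs). This equals the residual
standard deviation of a one-way subject-factor ANOVA, which the tests use
as an independent oracle. Derived quantities: `MDC = 1.96 sqrt(2) SEM`;
Lin's CCC with population (1/n) moments; Bland–Altman bias ± 1.96 sample
SD of the differences; and per-group sample size
`ceiling(2 (z_{1-a/2} + z_power)^2 / delta^2)` (normal approximation,
cross-checked against numerical power search; a t-based refinement is out
of scope). "Power 0.9" is read conventionally as power = 0.9. The
sample-size reduction between two methods powers the standardized
difference with each method's SEM via `delta = effect / (sqrt(2) SEM)`.

Bootstrap confidence intervals resample subjects with pairs intact;
percentile intervals are the default, BCa an option. A calibration fact
worth knowing: in simulation (n = 50 Gaussian pairs, 2000 datasets,
n_boot = 500) the 95% percentile interval for the CoV covers the true
value ~91% of the time, missing almost entirely on the high side; BCa
reaches ~92%. The cause is the heavy right skew of squared paired
differences (scaled chi-square with one degree of freedom), for which
bootstrap intervals on a mean are known to undercover at this sample size.
Users comparing CoVs near a decision threshold should treat the upper
confidence limit as optimistic at n ≈ 50.

## 7. Simulation design choices

Two evaluation designs need recording because the obvious versions are
ill-posed for a deterministic, oracle-segmented pipeline:

* **Discretisation convergence.** At 1 mm pixels the volume error is
  already at the in-plane pixelisation noise floor (~0.3%), so refining
  only the slice spacing moves the single-run error randomly. The
  convergence check therefore refines pixel and slice spacing together —
  (2 mm, 8 mm) → (1 mm, 4 mm) → (0.5 mm, 2 mm) — and measures the RMS
  error over five jittered slice prescriptions per resolution: RMS EDV
  error falls 0.42% → 0.19% → 0.03%, monotone for EDV, ESV and LVM.
* **Scan-rescan perturbation levels.** The oracle pipeline's only
  scan-rescan error is discretisation, which decorrelates completely once
  planes move by about a pixel; CoV then saturates near 0.27% regardless
  of perturbation size. The perturbation sweep therefore sits in the
  sub-pixel regime — (translation, rotation, slice shift) =
  (1.5 mm, 1.5°, 1 mm) scaled by 0.1 / 0.3 / 1.0 over 20 subjects — where
  the measured EDV CoV rises strictly (0.097% / 0.160% / 0.267%) and is
  exactly 0 at zero perturbation.

Problem sizes used by the test suite and the acceptance script (3 subjects
for the determinism check, 20 for the perturbation sweep, 2000x500 for
bootstrap coverage, 200 training slices at 64x64 for the toy network) are
chosen so the full evaluation runs in minutes on one CPU while keeping
every Monte-Carlo margin comfortable.

## 8. Known limitations

* Through-plane resolution is the dominant error source at clinical slice
  spacing; no super-resolution or 3D surface reconstruction is attempted.
* The valve-plane correction assumes consistent breath-holds; the
  `breathhold_offset()` model quantifies the resulting bias but the
  pipeline does not correct it.
* The U-net is CPU-scale; no GPU path, no multi-site training, and no
  claim of robustness to image appearance beyond the phantom's.
* Precision simulations inherit the phantom's idealisations: real
  scan-rescan CoV includes segmentation and physiological variability that
  the oracle path deliberately excludes.
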