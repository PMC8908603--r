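# cmrlv

Automated left-ventricular (LV) volumetry for multi-plane cine cardiac MRI
(CMR), with the statistical machinery to quantify how precise such a
pipeline is.

Cine CMR is the reference standard for measuring LV volumes, ejection
fraction and myocardial mass, but manual contouring introduces intra- and
inter-observer variability that propagates into clinical decisions and
trial sample sizes. `cmrlv` implements a fully automated analysis chain for
a standard acquisition (a short-axis cine stack plus 2-chamber and
4-chamber long-axis cines) and a scan-rescan precision evaluation
framework, together with a synthetic ventricle phantom whose volumes are
known in closed form — so every stage can be validated end to end without
clinical data.

## What the pipeline does

1. **Spatial normalisation.** Using DICOM-convention plane geometry
   (origin, direction cosines, pixel spacing), the short-axis (SAx) stack
   is anchored at the intersection point of the mid SAx, 2-chamber and
   4-chamber planes, rotated so the SAx/2Ch intersection aligns with the
   y-axis, and resampled in-plane to 1 mm pixels.
2. **Segmentation.** A pluggable segmenter labels each slice as background
   / LV blood pool / myocardium. Two implementations ship: an analytic
   oracle backed by the phantom's geometry, and a small trainable U-net
   (dilated bottleneck convolutions, batch normalisation, softmax over 3
   classes, Adam at learning rate 1e-4 by default).
3. **Mitral valve (MV) plane.** The two mitral annular points in each
   long-axis view are encoded as Gaussian-weighted distance maps
   `exp(-d^2 / 2σ^2)` (the regression target a landmark U-net predicts),
   decoded with sub-pixel refinement, and a plane is fitted to the four
   points by total least squares, oriented with the ventricle on the
   positive side.
4. **Volumetry.** Per phase, slice masks are integrated as contiguous
   slabs (Simpson's method, slab thickness = inter-slice spacing); each
   pixel column is fractionally clipped against the MV plane so volume on
   the atrial side is discarded. End-diastole (ED) is the phase with the
   largest blood volume and end-systole (ES) the smallest, giving

   EDV, ESV, SV = EDV − ESV, LVEF = 100·SV/EDV, LVM = 1.05 g/ml · V_myo(ED).

5. **Quality control.** Automated plausibility flags mark defects touching
   ≥ 5% of the cardiac volume: extra blood-pool components unsupported by
   adjacent slices, slice-to-slice area jumps, detached myocardium, and
   high MV-plane fit residuals (a signature of breath-hold mismatch between
   acquisitions).

For precision evaluation, `run_precision()` analyses scan/rescan pairs and
reports, per metric: within-subject coefficient of variation by the
root-mean-squared method (CoV = 100·SEM/mean with
SEM = sqrt(Σdᵢ²/2n)), bootstrap confidence intervals (percentile,
optionally BCa), Lin's concordance correlation coefficient, Bland–Altman
bias and limits of agreement, the minimal detectable change
MDC = 1.96·√2·SEM, and normal-approximation trial sample sizes.

## The phantom

`phantom_spec()` / `generate_study()` build a truncated-ellipsoid blood
pool with a uniform myocardial shell, contracting isotropically over the
cardiac cycle so that every phase has a closed-form volume and the
ejection fraction hits its target exactly. The generator emits a full
multi-plane cine study — SAx stack, 2Ch and 4Ch views with genuine plane
geometry, grayscale images, 3-class masks, annulus landmarks — plus the
analytic ground truth. `rescan()` re-prescribes the imaging planes
(scan-rescan variability), and `breathhold_offset()` shifts the long-axis
plane headers against the SAx stack (the classic basal over/under-trimming
failure mode).

## Worked example

```r
library(cmrlv)

spec <- phantom_spec(seed = 7)          # 117 ml EDV, EF 60%, 30 phases
g <- generate_study(spec)
print(g$truth)
#> <phantom_truth: EDV 117.3 ml, ESV 46.9 ml, EF 60.0%, LVM 113.9 g>

report <- run_study(g$study, oracle_segmenter(g$truth))
print(report)
#> LV metrics: EDV 116.9 ml | ESV 46.6 ml | SV 70.3 ml | EF 60.1% | LVM 113.8 g
#>   ED phase 1, ES phase 16
#> QC: no flags
```

The pipeline recovers the analytic EDV within 0.4% and the ejection
fraction within 0.2 EF-points; re-running on the same study reproduces the
numbers bit for bit (the algorithm is deterministic, so its intra-run CoV
is exactly 0%).

Scan-rescan precision over five simulated subjects:

```r
subjects <- lapply(1:5, function(i) {
  gi <- generate_study(random_phantom_spec(100 + i))
  ri <- rescan(gi$study, gi$truth,
               list(translation = 1.5, rotation_deg = 1.5, slice_shift = 1),
               seed = 200 + i)
  list(scan = gi$study, rescan = ri$study, truth = gi$truth)
})
pr <- run_precision(subjects, segmenter = "oracle", n_boot = 1000, seed = 1)
format_precision_table(pr$reports)
#>        metric            cov   sem   mdc    ccc   bias mean_abs_diff n
#> edv_ml edv_ml 0.3% (0.1-0.4) 0.258 0.715 0.9996  0.002         0.305 5
#> esv_ml esv_ml 0.4% (0.2-0.5) 0.171 0.473 0.9993  0.055         0.202 5
#> sv_ml   sv_ml 0.6% (0.3-0.9) 0.292 0.809 0.9993 -0.053         0.381 5
#> ef_pct ef_pct 0.4% (0.2-0.6) 0.229 0.636 0.9987 -0.091         0.298 5
#> lvm_g   lvm_g 0.2% (0.2-0.3) 0.263 0.729 0.9998  0.051         0.333 5
```

With an oracle segmenter the only scan-rescan error is slice-prescription
discretisation, so these CoVs (~0.3%) are the geometric noise floor of the
volumetry itself — an order of magnitude below typical human scan-rescan
CoV.

A thin command-line interface wraps the same functions:

```sh
inst/cli/cmrlv phantom --seed 7 --out study/
inst/cli/cmrlv analyze study/ --segmenter oracle --out report.json
inst/cli/cmrlv precision --subjects 10 --out precision
```

## Scope

The package analyses the left ventricle only (no right ventricle, atria,
strain or late-gadolinium analysis), treats short-axis slices
independently in-plane (no through-plane super-resolution or 3D meshing),
and does not correct for motion between phases. The trainable U-net is a
toy-scale component for validating the architecture and training loop on
phantom data; it makes no claim to clinical-grade segmentation.
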