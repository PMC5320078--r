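---
title: "Ventricle segmentation in non-contrast head CT with stroke exclusion: models and design"
author: "ventriseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ventricle segmentation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventriseg)
```

## The problem

On non-contrast head CT of ischemic-stroke patients, the cerebral
ventricles (cerebrospinal fluid, roughly 1-12 HU) and ischemic lesions
(hypodense infarcted tissue, roughly 8-25 HU) overlap in attenuation, and
large infarcts frequently abut or touch the ventricular system. A plain
intensity threshold therefore cannot separate ventricle from stroke, yet an
accurate ventricle mask is a prerequisite for automated stroke detection
and for ventricular volumetry. `ventriseg` implements a fully objective
(parameter-free at run time) segmentation pipeline that combines brain
alignment with three stroke-exclusion schemes, plus a synthetic phantom
generator and an evaluation suite, so that every stage is testable without
clinical data.

The pipeline, in order:

1. **Skull stripping.** Bone is everything at or above a fixed 100 HU;
   the brain is the largest 3D region enclosed by bone (per-slice hole
   fill of the bone mask, minus bone, largest 26-connected component).
2. **Midsagittal alignment.** Falx-cerebri/interhemispheric light curves
   are detected per slice (vertical 7-tap Gaussian of variance 2, a
   zero-sum horizontal line mask (-0.5, 0, 1, 0, -0.5), an adaptive
   threshold at mean + 2.5 sd of the response, and a 3D 30-voxel
   component filter); a 3D plane `x = a*y + b*z + c` is fitted to the
   surviving edge voxels by least squares, and each slice is rigidly
   rotated/translated so the plane's in-slice trace coincides with the
   vertical centerline.
3. **Ventricular intensity range.** A deterministic 1D 2-means splits the
   brain intensities; the largest 3D component of the low class carries
   the CSF together with white matter, and the CSF/white-matter valley of
   its histogram yields the ventricular range `[vMin, vMax]`.
4. **Segmentation with stroke exclusion.** Preliminary mask
   `f(t) = {vMin <= HU <= t}` at `t = vMax`, largest 3D component; a
   brain-edge annulus detector decides whether a large stroke contaminates
   the result; if so, an integer bisection finds the critical threshold
   whose segmentation result is clean, and the image difference
   `PA = f(vMax) - g(benchmark)` extracts and removes the stroke. An
   adaptive template built from the image itself excludes small
   periventricular lesions, and morphological refinement produces the
   final mask.

## Coordinate and boundary conventions

All geometry lives in 1-based voxel index space with `x` the column
(left-right), `y` the row (anterior-posterior) and `z` the slice, matching
R's array indexing; physical distances enter only through the voxel
spacing (0.426 mm in-plane, 5 mm slices by default), e.g. for the boundary
RMSE. One-sided rules are fixed once: a voxel at exactly 100 HU is bone; a
3D edge component of exactly 30 voxels survives; an annulus overlap of
exactly 20 px does **not** trigger stroke detection (strict inequality);
ties among equal-sized 3D components go to the component first reached in
raster order, which the deterministic Rcpp labeling makes reproducible.
Connected components are 26-connected in 3D throughout (the in-plane
morphology -- closing, dilation, hole filling -- is 2D per slice, because
5 mm slices make 3D structuring elements severely anisotropic).

## The alignment model

The printed form of the plane fit in the source method parametrises the
plane as `z = f(x, y)`, which is degenerate for a near-vertical sagittal
plane, and its alignment matrix is not a proper rotation (both
off-diagonal terms share a sign, so the determinant is `cos 2theta`).
`ventriseg` fits `x = a*y + b*z + c` -- well-conditioned for sagittal
planes, with `atan(a)` the in-slice inclination -- and applies the proper
rotation about the image centre followed by the horizontal shift that
centres the midsagittal line. HU values are interpolated bilinearly
(out-of-frame voxels become -1000 HU); masks use nearest neighbour. The
fitted plane is validated against an independent SVD-based total
least-squares fit on exact-plane data in the test suite.

Two practical details protect the least-squares fit from structured
contamination, both standard practice and both recorded in the run log:

* non-brain pixels are replaced by the slice's mean brain intensity before
  filtering (a zeroed background would turn the brain-mask staircase into
  spurious line responses), and
* the brain mask is eroded by 3 px in-plane for the detection step only,
  excluding the bright partial-volume rim of the inner skull table.

The 2.5 sd threshold keeps any sufficiently strong, vertically coherent
edge, so the surviving map contains the fissure/falx bundle on the midline
together with ventricle-wall edges a few tens of pixels off it. Because
the anatomy is mirror-symmetric about the midsagittal plane, those wall
edges enter the fit symmetrically; the long interhemispheric fissure
dominates the cloud and anchors both the slope and the intercept. When no
component survives the 30-voxel filter, the pipeline falls back to the
vertical plane through the brain bounding-box centre and flags it.

Limitation: a very large hypodense lesion adds *asymmetric* step edges
inside the detection ROI and can bias the plain least-squares fit by one
to a few degrees. On lesion-free phantoms the tilt recovery is well inside
one degree; under the heavy-lesion evaluation conditions roughly four of
five cases stay inside one degree. The segmentation stages downstream are
essentially rotation-invariant, so this bias does not propagate to the
overlap metrics.

## The intensity model

With K = 2 on brain intensities, the optimal 1D split lands *inside* the
parenchyma (CSF is only a few percent of the brain volume), so the low
class is white matter plus CSF. This is what the histogram step expects:
within the rough ventricular band (up to 12 HU, domain knowledge) the
candidate component's histogram shows the CSF peak; above it lies the
partial-volume valley and then the white-matter rise. The estimator
smooths the per-HU histogram with a 3-bin moving average, finds the CSF
mode inside the rough band, descends until the counts fall below half the
peak, and collects the *valley floor*: bins whose smoothed slope is
non-negative or within 2% of the peak count, stopping once counts rebound
past twice the running minimum. The critical intensity is the midpoint of
the floor bins lying within that same tolerance of the floor minimum -- a
bare argmin would jitter with count noise, while the full floor run
drifts with its entry and exit points. `vMax` is the critical intensity;
`vMin` mirrors the mode (`mode - (critical - mode)`, clamped at 0); both
are clamped into a [-5, 25] HU sanity band. A histogram with no usable
valley (e.g. a single spike) falls back to the domain-knowledge range
(1, 12) HU with a flag.

The 2-means itself is deterministic: centres start at the 10th and 90th
percentiles (falling back to the extremes when those coincide) and Lloyd
iterations run to a fixed point of the *assignment*, not merely of the
centres, so boundary values cannot be left mid-flip. On bimodal data with
CSF-versus-parenchyma separation this fixed point coincides with the
exhaustive optimal split, which the test suite verifies; for heavily
overlapping mixtures K-means is by nature a local optimiser.

## The segmentation model

**Annulus detector.** Large (MCA/ACA-territory) infarcts hug the brain
edge. The annulus is the per-slice set of brain voxels within
`0.15 * Lmin` of the brain boundary (Euclidean distance transform), with
`Lmin` the minimum side of the scan-wide brain bounding rectangle. A
segmentation "object" triggers detection when its per-slice overlap with
the annulus strictly exceeds 20 px.

**Critical-threshold search.** The detection predicate applied to the
largest component of `f(t)` is monotone in `t` on this geometry (a growing
threshold only grows the lesion and its annulus overlap), so the largest
clean integer threshold is found by bisection over the integer lattice in
`[vMin, vMax]`; the tests confirm the bisection equals an exhaustive
integer scan on every suite case. Golden-section search, which the source
method names, targets unimodal continuous objectives; for a monotone
boolean predicate integer bisection returns the same threshold and
provably terminates. If even the bottom of the range is contaminated, the
search returns `vMin` with a warning -- the annulus restriction in the
extraction step still protects the ventricle in that case.

**Image difference.** The subtrahend of the difference is the *benchmark
ventricular mask*: the segmentation **result** at the critical threshold,
i.e. the largest 3D component, which the search has certified clean -- not
the raw threshold mask, which for a large lesion still contains the
lesion's sub-threshold core and would shield it from the difference. The
benchmark is consolidated by `g(.)`: per-slice closing (disk r = 2)
followed by dilation (r = 1, removing lesion margins). `PA = f(vMax) -
g(benchmark)` is restricted to 3D components overlapping the annulus
(stroke is edge-adjacent), and the ventricle mask is `f(vMax) - g(PA)`.

**Adaptive template.** The template thresholds at `vMin`; since `vMin` is
the band's lower bound and typically selects almost nothing, the level
falls back to the band midpoint whenever fewer than 100 voxels result
(both levels are logged). The largest 3D component is closed (r = 2) and
dilated (r = 3). When a stroke was extracted, the template is built on
the brain *minus* the dilated stroke region; otherwise a large in-band
lesion could itself become the template's largest component and invert
the exclusion. Applying the template removes segmentation components with
no template overlap; within retained components, out-of-template voxels
forming per-slice 2D patches of 20 px or more are removed (lesion bulges
-- removing them also severs the 3D bridge between lesion and ventricle,
so the final largest-component step drops the remainder), while smaller
patches are kept so the genuine ventricular rim is not nibbled away.

**Refinement.** Largest 3D component, per-slice closing (r = 2), removal
of voxels brighter than `vMax + 30` HU (calcifications pulled in by the
closing; the margin is configurable), final largest component.

**Native-grid output.** The final mask is computed in aligned space but
reported on the input grid. Interior voxels follow the (bilinearly
sampled, 0.5-thresholded) resampled mask, so closing-filled holes
survive; within a one-voxel band around the boundary the decision is
re-cut on the input volume's own HU against `[vMin, vMax]`, which places
the contour on the native grid instead of inheriting resampling
staircase. The band is forbidden from re-entering voxels the stroke or
template stages removed.

All tunables -- thresholds, radii, tolerances, the specificity domain --
live in a single `segConfig()` object with the published defaults; every
run logs the effective configuration, and `readConfig()` loads overrides
from YAML.

## The phantom generator

The generator emulates the acquisition the method was designed for:
a 256 x 256 x 14 grid at 0.426 mm pixels and 5 mm slices (a 512 matrix is
available by argument; in-plane geometry scales with `min(nx, ny)/256`).
Its anatomy, drawn procedurally in an ideal (untilted) frame:

* a superellipse (exponent 2.7) skull ring at 1000 HU around gray matter
  (35-60 HU) with a feathered white-matter region (25-38 HU) -- axial head
  sections are flatter than an ellipse, and both the near-horizontal
  vertex boundary and the gradual white/gray transition are silent under
  a horizontal line detector, as in real CT;
* paired parasagittal lateral-ventricle bodies (straight bars parallel to
  the midline, tapered at the frontal and occipital horns) joined by a
  midline third-ventricle slit, all at 1-12 HU; the in-plane calibre
  scales per case to emulate anatomical ventricle-size variation;
* the interhemispheric fissure: a narrow CSF groove along the midline,
  anterior and posterior to the ventricles, on every slice, with the
  bright falx fold (gray value + 8 HU) drawn inside it on a
  Bernoulli(0.30) subset of slices -- the prevalence at which the falx is
  visible on axial CT;
* optional stroke lesions: edge-adjacent spheres (radius in mm, clipped
  to the brain, kept at least 4 px off the ventricle) or small
  periventricular spheres touching a lobe tangentially;
* rigid in-plane rotation (tilt) and translation, an in-plane Gaussian
  PSF (sigma 1 px) for partial volume, and additive Gaussian noise
  (3 HU). Truth masks undergo the same rigid motion (nearest neighbour)
  but are never blurred; background is -1000 HU (air).

`phantomSuite()` draws per-case tilt U(-15, 15) deg, shift U(-10, 10) px,
ventricle calibre U(0.7, 1.4) (switchable off for controlled alignment
experiments), edge-lesion radius U(5, 25) mm with HU low edge U(7, 11) and
width U(5, 8) -- ischemic hypodensity overlapping the upper ventricular
band -- and periventricular radius U(4, 8) mm with HU U(9, 12)+U(4, 6).
Per-case seeds derive from the master seed, and a manifest records every
draw. The evaluation mix is 20 edge-lesion, 5 periventricular, 5
lesion-free cases.

**What the phantom does not model**, and hence what passing tests do not
show about clinical data: beam hardening and streak artifacts, skull-base
anatomy, cortical sulci beyond the interhemispheric fissure,
through-plane partial volume (the PSF is in-plane only), hemorrhage,
anatomical asymmetry, and the texture of real parenchyma. The phantom is
cleaner than clinical CT; the published clinical means act as floors (or
ceilings, for error measures) for the synthetic experiment.

## Evaluation

Per case: Dice `2|Vs & Vr| / (|Vs| + |Vr|)`; voxel sensitivity and
specificity with the negative domain restricted to the brain mask by
default (full-frame negatives would inflate specificity towards 1
trivially; both options are in the config); boundary RMSE in mm over the
segmented mask's per-slice 8-connected boundary points, each matched to
the closest reference boundary point in the same slice (directional,
segmented to reference; slices with no reference boundary are skipped
with a warning); and volumes in ml. Suite level: mean/SD (n-1)/min/max
per metric, the reliability curve (strict fraction of cases with Dice
above d, sampled on d in [0.5, 1] step 0.01) and the product-moment
volume correlation, implemented from its sum form and cross-checked
against `stats::cor` in the tests.

One measurement subtlety is worth stating openly: against *independent*
synthetic ground truth, the boundary RMSE of a per-voxel thresholding
method has a floor of roughly half a pixel. The contour position jitters
by about `noise SD / edge slope` (~0.35 px at 3 HU noise over a ~9 HU/px
blurred edge), and the prediction's rasterisation is independent of the
truth's. A manual reference traced on the same noisy image shares the
image's noise-displaced edge, so reader-versus-algorithm RMSE largely
cancels that jitter; synthetic-truth RMSE cannot, and lands slightly
above the clinical figure even when the segmentation is at its response
optimum.

## Problem sizes

The bundled experiments use 30 phantoms of 256 x 256 x 14 voxels for the
full evaluation, 20 lesion-free phantoms for alignment parameter
recovery, exhaustive-scan cross-checks on all 30 cases, and 20 random
small mask pairs for the boundary-RMSE oracle; these sizes give stable
suite statistics while keeping a full run in the minutes range on one
CPU.

## A minimal run

```{r example, eval = FALSE}
ph <- generatePhantom(phantomSpec(seed = 7, tiltDeg = 8,
  strokeSpec = list(list(placement = "edge", radiusMm = 18,
                         huRange = c(8, 14)))))
res <- segmentVentricle(ph$volume)
res
evaluateSegmentation(finalMask(res), ph$truth@ventricleMask,
                     ph$truth@brainMask)
```

The `scripts/acceptance.R` script at the repository root regenerates the
30-case suite and recomputes the aggregate metrics from scratch; see the
README for how to run it.
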