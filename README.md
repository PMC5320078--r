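# ventriseg

Objective segmentation of the brain ventricles in non-contrast head CT of
ischemic-stroke patients.

On CT, the cerebrospinal fluid of the ventricles (about 1–12 HU) and
ischemic infarcts (hypodense tissue, often 8–25 HU) overlap in
attenuation, and large infarcts frequently touch the ventricular system —
so a plain threshold cannot isolate the ventricles, yet an accurate
ventricle mask underpins stroke CAD and ventricular volumetry. This
package is for image-analysis researchers and neuroimaging pipeline
builders who need a reproducible, parameter-free ventricle mask from
axial head CT, plus the machinery to validate it: a synthetic head-CT
phantom generator with ground truth, and a full evaluation suite.

## Method

The pipeline couples midsagittal alignment with three stroke-exclusion
schemes:

1. **Alignment.** Skull stripped at a fixed 100 HU; falx/interhemispheric
   light curves detected per slice (vertical 7-tap Gaussian, variance 2;
   horizontal line mask (−0.5, 0, 1, 0, −0.5); threshold mean + 2.5 sd;
   3D components under 30 voxels removed); midsagittal plane
   `x = a·y + b·z + c` fitted by least squares; each slice rigidly rotated
   by `atan(a)` and shifted so the midsagittal line is the vertical
   centerline.
2. **Intensity range.** Deterministic 1D 2-means stratifies the brain;
   the CSF/white-matter valley of the largest low-class component's
   histogram gives the ventricular range `[V_min, V_max]`.
3. **Segmentation with stroke exclusion.** With `f(t)` the band threshold
   `{V_min ≤ HU ≤ t}` inside the brain:
   * the largest 26-connected 3D component of `f(V_max)` is the initial
     segmentation (scheme 1: disconnected lesions drop out);
   * a brain-edge annulus of width `0.15·L_min` flags large edge-hugging
     infarcts (per-slice overlap strictly above 20 px); if flagged, an
     integer bisection finds the critical threshold `T_critical` whose
     largest component is clean, and the image difference
     `PA ≈ f(V_max) − g(f(T_critical))` (with `g` a morphological
     closing + dilation of the clean benchmark result) extracts the
     stroke, which is subtracted: `f(V_max) − g(PA)` (scheme 2);
   * an adaptive template — the largest component at a strict template
     threshold, closed and dilated — removes small periventricular
     lesions and severs lesion bridges (scheme 3); morphological
     refinement yields one final 3D component, reported on the input
     grid.

Evaluation implements Dice `2|V_s∩V_r|/(|V_s|+|V_r|)`, voxel
sensitivity/specificity (negatives restricted to the brain mask),
directional boundary RMSE in mm (closest reference boundary point per
segmented boundary point, per slice), the reliability curve
`ℛ(d) = #{Dice > d}/n`, and the product-moment volume correlation `R`.

## Worked example

Generate a phantom with an 18 mm edge-adjacent hypodense lesion, segment
it, and evaluate against the ground truth:

```r
library(ventriseg)

ph  <- generatePhantom(phantomSpec(seed = 7, tiltDeg = 8,
         strokeSpec = list(list(placement = "edge", radiusMm = 18,
                                huRange = c(8, 14)))))
res <- segmentVentricle(ph$volume)
res
#> SegmentationResult
#>   ventricular range [0.0, 20.0] HU, T_critical = 20.0
#>   stroke detected: FALSE
#>   final mask: 19102 voxels (17.33 ml)

evaluateSegmentation(finalMask(res), ph$truth@ventricleMask,
                     ph$truth@brainMask)
#>   id   dice sensitivity specificity rmseMm volSegMl volRefMl
#> 1 NA 0.9791      0.9894      0.9988 0.2224    17.33    16.97

sum(maskData(finalMask(res)) & maskData(ph$truth@strokeMask))
#> [1] 0
```

Reading the output: the intensity model estimated the ventricular band as
0–20 HU; the annulus detector stayed quiet (`stroke detected: FALSE`)
because this lesion, though 20 000 voxels large, is 3D-disconnected from
the ventricle and already fell to the largest-component rule, so
`T_critical` stayed at `V_max`. The final mask overlaps the truth at Dice
0.979 with a mean boundary error of 0.22 mm (about half a pixel) and
contains none of the 20 381 lesion voxels. Larger lesions that do merge
with the initial segmentation trigger the threshold search and image
difference instead; `res@log` narrates every decision.

A thin command-line front end wraps the same functions:

```sh
exec/ventriseg simulate --n 30 --seed 7 --out phantoms --stroke mix
exec/ventriseg segment phantoms/case001.nii.gz --out mask.nii.gz \
    --save-intermediates inter
exec/ventriseg evaluate mask.nii.gz phantoms/case001_ventricle.nii.gz \
    --brain phantoms/case001_brain.nii.gz --out report.csv
```

Input volumes may be NIfTI (`.nii`/`.nii.gz`) or a directory holding one
uncompressed little-endian DICOM series (rescale slope/intercept applied,
slices sorted along the normal).

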