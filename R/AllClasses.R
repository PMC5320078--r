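#' @import methods
#' @importFrom stats sd rnorm runif quantile
NULL

#' CT volume in Hounsfield units
#'
#' A 3D scalar field in Hounsfield units (HU) with anisotropic voxel spacing.
#' Voxel indices are 1-based with x = column (left-right), y = row
#' (anterior-posterior) and z = slice, matching R's array indexing; all
#' geometry in the package is expressed in this index space and converted to
#' millimetres through \code{spacing} only where physical distances are
#' reported.
#'
#' @slot voxels 3D numeric array of HU values (rescale already applied).
#' @slot spacing numeric(3), voxel spacing (dx, dy, dz) in mm.
#' @export
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric"),
  validity = function(object) {
    d <- dim(object@voxels)
    if (length(d) != 3) return("voxels must be a 3D array")
    if (d[3] < 3) return("volumes must have at least 3 slices")
    if (length(object@spacing) != 3 || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      return("spacing must be 3 positive finite values (mm)")
    TRUE
  })

#' Binary mask aligned with a CTVolume
#'
#' @slot mask 3D logical array.
#' @slot spacing numeric(3), voxel spacing in mm (inherited from the parent
#'   volume).
#' @export
setClass("BinaryVolume",
  representation(mask = "array", spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@mask)) != 3) return("mask must be a 3D array")
    if (!is.logical(object@mask)) return("mask must be logical")
    if (length(object@spacing) != 3 || any(object@spacing <= 0))
      return("spacing must be 3 positive values (mm)")
    TRUE
  })

#' Fitted 3D midsagittal plane
#'
#' Coefficients (a, b, c) of the plane x = a*y + b*z + c in voxel index
#' space. Its intersection with slice z is the per-slice midsagittal line
#' (MSL) x = a*y + (b*z + c), a near-vertical line whose in-slice angle to
#' the vertical is atan(a).
#'
#' @slot a,b,c numeric plane coefficients.
#' @slot residualRMS root-mean-square fit residual (voxels).
#' @slot nPoints number of edge points used in the fit.
#' @slot fallback logical; TRUE when too few falx edge points were found and
#'   the plane defaulted to the vertical plane through the brain
#'   bounding-box centre.
#' @export
setClass("MidsagittalPlane",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 residualRMS = "numeric", nPoints = "numeric",
                 fallback = "logical"),
  prototype(fallback = FALSE),
  validity = function(object) {
    if (!all(is.finite(c(object@a, object@b, object@c))))
      return("plane coefficients must be finite")
    if (abs(object@a) >= tan(30 * pi / 180))
      return("in-slice MSL angle exceeds 30 degrees; not a sagittal plane")
    TRUE
  })

#' Rigid in-plane alignment transform
#'
#' Per-slice rotation by theta about the image centre followed by a
#' horizontal translation that maps the midsagittal line onto the vertical
#' centerline. The rotation angle is shared by all slices (the MSL's
#' in-slice inclination); the translation varies per slice through the
#' plane's z term.
#'
#' @slot theta rotation angle (radians) applied to correct the inclination.
#' @slot center numeric(2) rotation centre (x0, y0) in voxel indices.
#' @slot shiftX numeric, per-slice horizontal shift (voxels).
#' @slot dims integer(3), the grid the transform was built for.
#' @export
setClass("AlignmentTransform",
  representation(theta = "numeric", center = "numeric", shiftX = "numeric",
                 dims = "integer"))

#' Estimated ventricular intensity range
#'
#' @slot vMin,vMax estimated ventricular HU bounds.
#' @slot criticalIntensity HU value at the histogram valley separating CSF
#'   from partial-volume/white matter.
#' @slot histogram data.frame with per-HU counts (hu, count, smoothed) of the
#'   candidate ventricle component.
#' @slot fallback logical; TRUE when no valley was found and the domain
#'   defaults (1, 12) HU were used.
#' @export
setClass("IntensityRange",
  representation(vMin = "numeric", vMax = "numeric",
                 criticalIntensity = "numeric", histogram = "data.frame",
                 fallback = "logical"),
  prototype(fallback = FALSE),
  validity = function(object) {
    if (object@vMin >= object@vMax) return("vMin must be < vMax")
    if (object@vMin < -5 || object@vMax > 60)
      return("ventricular range outside the brain-tissue band [-5, 60] HU")
    TRUE
  })

#' Result of the brain-edge stroke check / extraction
#'
#' @slot detected logical; TRUE when a segmented object overlaps the
#'   brain-edge annulus above the area threshold on some slice.
#' @slot offendingRegions BinaryVolume of the 3D components contributing the
#'   overlap.
#' @slot paMask BinaryVolume; the extracted stroke regions (the image
#'   difference PA), empty until extraction.
#' @export
setClass("StrokeFinding",
  representation(detected = "logical", offendingRegions = "BinaryVolume",
                 paMask = "BinaryVolume"))

#' Full segmentation result
#'
#' @slot preliminary largest 3D component of the v_max threshold mask
#'   (aligned space).
#' @slot tCritical the critical threshold found by the integer bisection
#'   search (equals vMax when no stroke is detected).
#' @slot stroke StrokeFinding.
#' @slot template BinaryVolume, the adaptive ventricle template (aligned
#'   space; may be empty when disabled).
#' @slot finalAligned BinaryVolume, final mask in aligned space.
#' @slot final BinaryVolume, final mask resampled back to the input grid.
#' @slot range IntensityRange used.
#' @slot plane MidsagittalPlane used for alignment.
#' @slot transform AlignmentTransform.
#' @slot log character vector of applied steps and decisions.
#' @export
setClass("SegmentationResult",
  representation(preliminary = "BinaryVolume", tCritical = "numeric",
                 stroke = "StrokeFinding", template = "BinaryVolume",
                 finalAligned = "BinaryVolume", final = "BinaryVolume",
                 range = "IntensityRange", plane = "MidsagittalPlane",
                 transform = "AlignmentTransform", log = "character"))

#' Synthetic head-CT phantom specification
#'
#' Parameters of the procedural head phantom: a superellipse skull ring
#' enclosing gray matter with a feathered white-matter region, a mirrored
#' pair of parasagittal lateral-ventricle bodies joined by a midline
#' third-ventricle slit, the interhemispheric fissure with a bright falx
#' fold on a random subset of slices, optional hypodense stroke lesions,
#' rigid in-plane rotation/translation, in-plane Gaussian partial-volume
#' blur, and additive Gaussian noise.
#'
#' @slot gridShape integer(3) (nx, ny, nz).
#' @slot pixelMm in-plane pixel size (mm).
#' @slot sliceMm slice thickness (mm).
#' @slot skullHu skull plateau value (HU).
#' @slot ventricleHuRange,whiteHuRange,grayHuRange per-tissue HU ranges the
#'   voxel values are drawn from uniformly.
#' @slot falxProbPerSlice Bernoulli probability that a slice shows a falx
#'   light curve.
#' @slot falxContrastHu additive brightness of the falx line (HU).
#' @slot tiltDeg head rotation about the slice axis, degrees in [-15, 15].
#' @slot shiftPx numeric(2) in-plane translation (x, y) in pixels.
#' @slot strokeSpec list of lesions; each a list with fields placement
#'   ("edge" or "periventricular"), radiusMm, huRange, and optionally
#'   center (x, y, z voxel indices).
#' @slot noiseSdHu additive Gaussian noise SD (HU).
#' @slot psfSigmaPx in-plane Gaussian PSF sigma (pixels) simulating partial
#'   volume.
#' @slot ventricleWidthScale in-plane ventricle calibre scale (anatomical
#'   size variation).
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", pixelMm = "numeric",
                 sliceMm = "numeric", skullHu = "numeric",
                 ventricleHuRange = "numeric", whiteHuRange = "numeric",
                 grayHuRange = "numeric", falxProbPerSlice = "numeric",
                 falxContrastHu = "numeric", tiltDeg = "numeric",
                 shiftPx = "numeric", strokeSpec = "list",
                 noiseSdHu = "numeric", psfSigmaPx = "numeric",
                 ventricleWidthScale = "numeric", seed = "integer"),
  validity = function(object) {
    rngOk <- function(r) length(r) == 2 && r[1] < r[2]
    if (length(object@gridShape) != 3 || any(object@gridShape < 1))
      return("gridShape must be 3 positive integers")
    if (object@pixelMm <= 0 || object@sliceMm <= 0)
      return("spacings must be positive")
    if (!rngOk(object@ventricleHuRange) || !rngOk(object@whiteHuRange) ||
        !rngOk(object@grayHuRange))
      return("all HU ranges must satisfy low < high")
    if (object@ventricleHuRange[2] > object@whiteHuRange[1] ||
        object@ventricleHuRange[2] > object@grayHuRange[1])
      return("ventricle HU range must be disjoint from white/gray (boundary overlap at most)")
    if (object@skullHu <= 100)
      return("skullHu must exceed 100 HU so the fixed skull threshold separates bone")
    if (abs(object@tiltDeg) > 15)
      return("tiltDeg must lie in [-15, 15]")
    if (object@falxProbPerSlice < 0 || object@falxProbPerSlice > 1)
      return("falxProbPerSlice must be a probability")
    if (object@noiseSdHu < 0 || object@psfSigmaPx < 0)
      return("noiseSdHu and psfSigmaPx must be non-negative")
    if (object@ventricleWidthScale < 0.5 || object@ventricleWidthScale > 1.5)
      return("ventricleWidthScale must lie in [0.5, 1.5]")
    TRUE
  })

#' Ground truth accompanying a generated phantom
#'
#' @slot ventricleMask,strokeMask,brainMask BinaryVolume truth masks,
#'   transformed rigidly with the phantom but never blurred.
#' @slot trueTiltDeg the applied head tilt (degrees).
#' @slot trueMslOffsetPx the applied horizontal midline shift (pixels).
#' @export
setClass("PhantomTruth",
  representation(ventricleMask = "BinaryVolume", strokeMask = "BinaryVolume",
                 brainMask = "BinaryVolume", trueTiltDeg = "numeric",
                 trueMslOffsetPx = "numeric"),
  validity = function(object) {
    v <- object@ventricleMask@mask; s <- object@strokeMask@mask
    b <- object@brainMask@mask
    if (any(v & s)) return("ventricle and stroke masks must be disjoint")
    if (any(v & !b) || any(s & !b))
      return("truth masks must be nested inside the brain mask")
    TRUE
  })
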