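#' Accessors for volume objects
#'
#' @param object a \code{CTVolume}, \code{BinaryVolume} or other package
#'   object.
#' @return \code{voxelData} returns the 3D numeric array of a
#'   \code{CTVolume}; \code{maskData} the logical array of a
#'   \code{BinaryVolume}; \code{spacing} the (dx, dy, dz) spacing in mm.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("maskData", function(object) standardGeneric("maskData"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setMethod("voxelData", "CTVolume", function(object) object@voxels)
#' @rdname accessors
#' @export
setMethod("maskData", "BinaryVolume", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("spacing", "CTVolume", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("spacing", "BinaryVolume", function(object) object@spacing)

#' @describeIn accessors estimated ventricular lower HU bound
#' @export
setGeneric("vMin", function(object) standardGeneric("vMin"))
#' @describeIn accessors estimated ventricular upper HU bound
#' @export
setGeneric("vMax", function(object) standardGeneric("vMax"))
#' @rdname accessors
#' @export
setMethod("vMin", "IntensityRange", function(object) object@vMin)
#' @rdname accessors
#' @export
setMethod("vMax", "IntensityRange", function(object) object@vMax)

#' @describeIn accessors final ventricle mask (input grid) of a
#'   \code{SegmentationResult}
#' @export
setGeneric("finalMask", function(object) standardGeneric("finalMask"))
#' @rdname accessors
#' @export
setMethod("finalMask", "SegmentationResult", function(object) object@final)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume: %d x %d x %d voxels, spacing %.3f x %.3f x %.3f mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "BinaryVolume", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BinaryVolume: %d x %d x %d, %d foreground voxels (%.2f ml)\n",
              d[1], d[2], d[3], sum(object@mask),
              sum(object@mask) * prod(object@spacing) / 1000))
})

setMethod("show", "MidsagittalPlane", function(object) {
  cat(sprintf(
    "MidsagittalPlane: x = %.4f*y + %.4f*z + %.2f (theta = %.2f deg)\n",
    object@a, object@b, object@c, atan(object@a) * 180 / pi))
  cat(sprintf("  fit on %d points, residual RMS %.3f px%s\n", object@nPoints,
              object@residualRMS,
              if (object@fallback) " [fallback: no light curve]" else ""))
})

setMethod("show", "IntensityRange", function(object) {
  cat(sprintf(
    "IntensityRange: [%.1f, %.1f] HU (critical intensity %.1f)%s\n",
    object@vMin, object@vMax, object@criticalIntensity,
    if (object@fallback) " [fallback defaults]" else ""))
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult\n")
  cat(sprintf("  ventricular range [%.1f, %.1f] HU, T_critical = %.1f\n",
              object@range@vMin, object@range@vMax, object@tCritical))
  cat(sprintf("  stroke detected: %s\n", object@stroke@detected))
  cat(sprintf("  final mask: %d voxels (%.2f ml)\n", sum(object@final@mask),
              sum(object@final@mask) * prod(object@final@spacing) / 1000))
})

setMethod("show", "PhantomSpec", function(object) {
  g <- object@gridShape
  cat(sprintf(
    "PhantomSpec: %d x %d x %d @ %.3f/%.1f mm, tilt %.1f deg, %d lesion(s)\n",
    g[1], g[2], g[3], object@pixelMm, object@sliceMm, object@tiltDeg,
    length(object@strokeSpec)))
})
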