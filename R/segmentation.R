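#' Threshold segmentation f(t)
#'
#' The preliminary threshold operator: brain voxels with
#' vMin <= HU <= t.
#'
#' @param vol a \code{CTVolume}.
#' @param brain brain mask.
#' @param t upper threshold (HU).
#' @param vMin lower ventricular bound (HU).
#' @return A \code{BinaryVolume}.
#' @export
thresholdSegment <- function(vol, brain, t, vMin) {
  checkSameGeometry(vol, brain)
  if (t < vMin) stop("threshold t must be >= vMin")
  binaryVolume(brain@mask & vol@voxels >= vMin & vol@voxels <= t,
               spacing = vol@spacing)
}

#' Largest 3D connected component
#'
#' 26-connected largest component; ties are broken toward the component
#' first encountered in raster order (deterministic labeling).
#'
#' @param mask a nonempty \code{BinaryVolume}.
#' @param cfg a \code{\link{segConfig}}.
#' @return A \code{BinaryVolume} holding only the largest component.
#' @export
largestComponent3D <- function(mask, cfg = segConfig()) {
  if (!any(mask@mask)) stop("empty mask has no largest component")
  lab <- labelComponents(mask@mask, cfg$connectivity)
  keep <- which.max(componentSizes(lab))
  binaryVolume(lab == keep, spacing = mask@spacing)
}

#' Brain-edge annulus
#'
#' Per slice, the brain voxels within 0.15 * Lmin of the brain boundary
#' (Euclidean distance), where Lmin is the minimum side length of the
#' scan-wide minimum bounding rectangle of the brain. Large
#' (MCA/ACA-territory) infarcts hug the brain edge, so objects overlapping
#' this band flag a stroke.
#'
#' @param brain brain mask.
#' @param cfg a \code{\link{segConfig}} (annulusWidthFrac).
#' @return A list: \code{mask} (annulus \code{BinaryVolume}),
#'   \code{widthPx}, \code{lMin}.
#' @export
annulusMask <- function(brain, cfg = segConfig()) {
  m <- brain@mask
  if (!any(m)) stop("empty brain mask")
  xs <- range(which(apply(m, 1, any)))
  ys <- range(which(apply(m, 2, any)))
  lMin <- min(diff(xs) + 1, diff(ys) + 1)
  w <- cfg$annulusWidthFrac * lMin
  dist <- distanceToBackgroundSlices(m)
  ann <- m & dist <= w
  list(mask = binaryVolume(ann, spacing = brain@spacing),
       widthPx = w, lMin = lMin)
}

#' Brain-edge stroke check
#'
#' Computes the per-slice overlap area between a segmentation and the
#' brain-edge annulus; a stroke is declared when any slice's overlap
#' strictly exceeds the 20 px area threshold. The offending regions are
#' the 3D components of the segmentation contributing those overlaps.
#'
#' @param seg segmentation mask.
#' @param annulus annulus mask (from \code{\link{annulusMask}}).
#' @param cfg a \code{\link{segConfig}}.
#' @return A \linkS4class{StrokeFinding} (paMask empty at this stage).
#' @export
edgeCheck <- function(seg, annulus, cfg = segConfig()) {
  checkSameGeometry(seg, annulus)
  ov <- seg@mask & annulus@mask
  areas <- apply(ov, 3, sum)
  bad <- areas > cfg$annulusAreaPx
  offending <- emptyMaskLike(seg)
  if (any(bad)) {
    lab <- labelComponents(seg@mask, cfg$connectivity)
    ids <- unique(lab[ov & rep(bad, each = prod(dim(seg@mask)[1:2]))])
    ids <- ids[ids > 0]
    offending <- binaryVolume(array(lab %in% ids, dim(seg@mask)),
                              spacing = seg@spacing)
  }
  new("StrokeFinding", detected = any(bad), offendingRegions = offending,
      paMask = emptyMaskLike(seg))
}

# Is threshold t free of edge-detected stroke? (empty segmentations count
# as clean: there is nothing to detect)
cleanAtThreshold <- function(vol, brain, t, vMin, annulus, cfg) {
  f <- thresholdSegment(vol, brain, t, vMin)
  if (!any(f@mask)) return(TRUE)
  lc <- largestComponent3D(f, cfg)
  !edgeCheck(lc, annulus, cfg)@detected
}

#' Critical-threshold search
#'
#' Finds the largest integer threshold t in [vMin, vMax] whose largest
#' 3D component passes the brain-edge check, exploiting the monotonicity
#' of the detection predicate in t with an integer bisection. If even the
#' bottom of the range triggers detection, vMin is returned with a
#' warning; if f(vMax) is already clean, t = vMax.
#'
#' @param vol aligned \code{CTVolume}.
#' @param brain brain mask.
#' @param range an \linkS4class{IntensityRange}.
#' @param annulus annulus (precomputed, optional).
#' @param cfg a \code{\link{segConfig}}.
#' @return Numeric t_critical (HU).
#' @export
findCriticalThreshold <- function(vol, brain, range, annulus = NULL,
                                  cfg = segConfig()) {
  vMin <- range@vMin; vMax <- range@vMax
  stopifnot(vMin < vMax)
  if (is.null(annulus)) annulus <- annulusMask(brain, cfg)$mask
  clean <- function(t) cleanAtThreshold(vol, brain, t, vMin, annulus, cfg)
  if (clean(vMax)) return(vMax)
  lo <- ceiling(vMin); hi <- floor(vMax)
  if (hi >= vMax) hi <- hi - 1          # vMax already known dirty
  if (hi < lo || !clean(lo)) {
    warning("stroke detected even at vMin; returning vMin")
    return(vMin)
  }
  if (clean(hi)) return(hi)
  # invariant: clean(lo), !clean(hi)
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (clean(mid)) lo <- mid else hi <- mid
  }
  lo
}

# g(*): morphological consolidation used by the image-difference scheme --
# in-plane closing followed by a dilation that removes lesion margins.
morphG <- function(mask, cfg, dilateR) {
  morphDilateSlices(morphCloseSlices(mask, cfg$closingR), dilateR)
}

#' Extract stroke regions by image difference
#'
#' PA = f(vMax) - g(benchmark), where the benchmark ventricular mask is
#' the stroke-free segmentation result at the critical threshold (the
#' largest 3D component of f(tCritical), which the threshold search
#' guarantees passes the brain-edge check) and g is a per-slice closing
#' (r = 2) plus dilation (r = 1). The difference is restricted to 3D
#' components that overlap the brain-edge annulus (stroke is
#' edge-adjacent).
#'
#' @param vol aligned \code{CTVolume}.
#' @param brain brain mask.
#' @param range an \code{IntensityRange}.
#' @param tCritical critical threshold from
#'   \code{\link{findCriticalThreshold}}.
#' @param annulus annulus mask (optional, recomputed when NULL).
#' @param cfg a \code{\link{segConfig}}.
#' @return A \linkS4class{StrokeFinding} with \code{paMask} filled in.
#' @export
extractStroke <- function(vol, brain, range, tCritical, annulus = NULL,
                          cfg = segConfig()) {
  stopifnot(tCritical <= range@vMax)
  if (is.null(annulus)) annulus <- annulusMask(brain, cfg)$mask
  fmax <- thresholdSegment(vol, brain, range@vMax, range@vMin)
  ftc <- thresholdSegment(vol, brain, tCritical, range@vMin)
  bench <- if (any(ftc@mask)) largestComponent3D(ftc, cfg)@mask else ftc@mask
  benchmark <- morphG(bench, cfg, cfg$strokeDilateR)
  pa0 <- fmax@mask & !benchmark
  pa <- array(FALSE, dim(pa0))
  if (any(pa0)) {
    lab <- labelComponents(pa0, cfg$connectivity)
    ids <- unique(lab[annulus@mask & pa0])
    ids <- ids[ids > 0]
    if (length(ids)) pa <- array(lab %in% ids, dim(pa0))
  }
  paBV <- binaryVolume(pa, spacing = vol@spacing)
  new("StrokeFinding", detected = any(pa), offendingRegions = paBV,
      paMask = paBV)
}

#' Remove extracted stroke from a segmentation
#'
#' The ventricle mask f(vMax) - g(PA): the stroke mask is closed and
#' dilated (stroke margins included) before subtraction.
#'
#' @param seg segmentation mask (typically f(vMax)).
#' @param stroke a \code{StrokeFinding} (its \code{paMask} is subtracted).
#' @param cfg a \code{\link{segConfig}}.
#' @return A \code{BinaryVolume}.
#' @export
subtractStroke <- function(seg, stroke, cfg = segConfig()) {
  pa <- stroke@paMask
  checkSameGeometry(seg, pa)
  if (!any(pa@mask)) return(seg)
  binaryVolume(seg@mask & !morphG(pa@mask, cfg, cfg$strokeDilateR),
               spacing = seg@spacing)
}

#' Build the adaptive ventricle template
#'
#' Thresholds at the template level (vMin; when that selects fewer than
#' 100 voxels, the band midpoint (vMin + vMax) / 2), keeps the largest 3D
#' component, and consolidates it with per-slice closing (r = 2) and
#' dilation (r = 3). The template covers the main body of the lateral
#' ventricles without claiming the full ventricular system.
#'
#' @param vol aligned \code{CTVolume}.
#' @param brain brain mask (pass the stroke-free brain when a stroke was
#'   extracted, so a large in-band lesion cannot become the template).
#' @param range an \code{IntensityRange}.
#' @param cfg a \code{\link{segConfig}}.
#' @return A \code{BinaryVolume}; empty when no template can be formed
#'   (small-lesion exclusion is then skipped).
#' @export
buildTemplate <- function(vol, brain, range, cfg = segConfig()) {
  core <- thresholdSegment(vol, brain, range@vMin, range@vMin)
  level <- range@vMin
  if (sum(core@mask) < cfg$templateMinVox) {
    level <- (range@vMin + range@vMax) / 2
    core <- thresholdSegment(vol, brain, level, range@vMin)
  }
  if (!any(core@mask)) {
    warning("template disabled: no voxels at the template threshold")
    return(emptyMaskLike(vol))
  }
  core <- largestComponent3D(core, cfg)
  tpl <- morphDilateSlices(morphCloseSlices(core@mask, cfg$closingR),
                           cfg$templateDilateR)
  binaryVolume(tpl, spacing = vol@spacing)
}

#' Apply the adaptive template
#'
#' The template and segmentation share the MSL alignment, so registration
#' is the identity. 3D components of the segmentation with no template
#' overlap are removed. Within retained components, out-of-template voxels
#' forming per-slice 2D patches of 20 px or more are removed (these are
#' lesion bulges; removing them also breaks the 3D bridge between lesion
#' and ventricle), while smaller out-of-template patches are kept so the
#' genuine ventricle rim is not nibbled away.
#'
#' @param seg segmentation mask.
#' @param template template mask; when empty the segmentation passes
#'   through unchanged.
#' @param cfg a \code{\link{segConfig}}.
#' @return A \code{BinaryVolume}.
#' @export
applyTemplate <- function(seg, template, cfg = segConfig()) {
  checkSameGeometry(seg, template)
  if (!any(template@mask)) return(seg)
  if (!any(seg@mask)) return(seg)
  lab <- labelComponents(seg@mask, cfg$connectivity)
  ids <- unique(lab[template@mask & seg@mask])
  ids <- ids[ids > 0]
  kept <- array(lab %in% ids, dim(seg@mask))
  outside <- kept & !template@mask
  if (any(outside)) {
    d <- dim(outside)
    for (z in seq_len(d[3])) {
      sl <- outside[, , z]
      if (!any(sl)) next
      lab2 <- labelComponents(array(sl, c(d[1], d[2], 1L)), 26L)
      sz <- componentSizes(lab2)
      big <- which(sz >= cfg$appendagePx)
      if (length(big)) {
        drop <- array(lab2 %in% big, c(d[1], d[2]))
        k <- kept[, , z]
        k[drop] <- FALSE
        kept[, , z] <- k
      }
    }
  }
  binaryVolume(kept, spacing = seg@spacing)
}

#' Refine the ventricle mask
#'
#' Largest 3D component, per-slice morphological closing (r = 2) to smooth
#' the ventricular edges, removal of calcifications pulled in by the
#' closing (voxels brighter than vMax + 30 HU), and a final largest
#' component.
#'
#' @param vol aligned \code{CTVolume} (for the calcification HU check).
#' @param seg segmentation mask.
#' @param vMax upper ventricular bound (HU).
#' @param cfg a \code{\link{segConfig}}.
#' @return A \code{BinaryVolume}.
#' @export
refineMask <- function(vol, seg, vMax, cfg = segConfig()) {
  if (!any(seg@mask)) stop("segmentation failure: empty mask before refinement")
  m <- largestComponent3D(seg, cfg)@mask
  m <- morphCloseSlices(m, cfg$closingR)
  m <- m & !(vol@voxels > vMax + cfg$calcificationMarginHu)
  if (!any(m)) stop("segmentation failure: refinement removed all voxels")
  largestComponent3D(binaryVolume(m, spacing = vol@spacing), cfg)
}

# Map the aligned-space final mask onto the input grid. Interior voxels
# follow the (bilinearly sampled) mask, so closing-filled holes survive;
# within a one-voxel band around the mask boundary the decision is re-cut
# on the input volume's own HU values, which places the final contour on
# the native grid instead of inheriting resampling jitter.
maskToInputGrid <- function(finalA, transform, vol, range, cfg,
                            excludedA = NULL) {
  innerA <- binaryVolume(morphErodeSlices(finalA@mask, 1L),
                         spacing = finalA@spacing)
  outerA <- binaryVolume(morphDilateSlices(finalA@mask, 1L),
                         spacing = finalA@spacing)
  inner <- resampleMaskToInput(innerA, transform)@mask
  outer <- resampleMaskToInput(outerA, transform)@mask
  if (!is.null(excludedA) && any(excludedA@mask)) {
    # never re-enter voxels the stroke/template exclusion stages removed
    excl <- resampleMaskToInput(excludedA, transform)@mask
    outer <- outer & !excl
  }
  inBand <- vol@voxels >= range@vMin & vol@voxels <= range@vMax
  out <- binaryVolume(inner | (outer & inBand), spacing = vol@spacing)
  if (any(out@mask)) out <- largestComponent3D(out, cfg)
  out
}

#' Segment the brain ventricles in a head CT
#'
#' Full pipeline: skull stripping (fixed 100 HU), falx light-curve
#' detection and 3D midsagittal-plane alignment, ventricular intensity
#' range estimation (2-means + histogram-slope tracking), preliminary
#' thresholding at vMax with largest-3D-component selection, the
#' brain-edge annulus stroke check, and -- when a stroke is detected --
#' image-difference removal via the critical-threshold search, followed by
#' adaptive-template exclusion of small periventricular lesions and
#' morphological refinement. The final mask is resampled back onto the
#' input grid.
#'
#' @param vol a \code{CTVolume} in HU.
#' @param cfg a \code{\link{segConfig}}.
#' @return A \linkS4class{SegmentationResult}.
#' @examples
#' ph <- generatePhantom(phantomSpec(gridShape = c(128, 128, 9), seed = 7))
#' res <- segmentVentricle(ph$volume)
#' res
#' @export
segmentVentricle <- function(vol, cfg = segConfig()) {
  logLines <- c(sprintf("config: %s", paste(formatConfig(cfg), collapse = "; ")))
  note <- function(...) logLines <<- c(logLines, sprintf(...))

  brain <- stripSkull(vol, cfg)
  note("skull stripped: %d brain voxels", sum(brain@mask))

  lc <- detectLightCurves(vol, brain, cfg)
  plane <- fitMidsagittalPlane(lc$points)
  if (is.null(plane)) {
    plane <- fallbackPlane(brain)
    note("no light curve detected; fallback vertical MSL at x = %.1f", plane@c)
  } else {
    note("midsagittal plane fit on %d points (theta %.2f deg, residual %.2f px)",
         plane@nPoints, atan(plane@a) * 180 / pi, plane@residualRMS)
  }

  al <- alignVolume(vol, plane)
  volA <- al$volume
  brainA <- applyTransformMask(brain, al$transform)

  cl <- clusterBrain(volA, brainA, cfg)
  range <- estimateVentricleRange(volA, cl$candidate, cfg)
  note("ventricular range [%.1f, %.1f] HU (critical %.1f%s)", range@vMin,
       range@vMax, range@criticalIntensity,
       if (range@fallback) ", fallback defaults" else "")

  ann <- annulusMask(brainA, cfg)
  fmax <- thresholdSegment(volA, brainA, range@vMax, range@vMin)
  if (!any(fmax@mask)) stop("segmentation failure: empty threshold mask")
  prelim <- largestComponent3D(fmax, cfg)
  check <- edgeCheck(prelim, ann$mask, cfg)
  note("edge check on preliminary segmentation: %s",
       if (check@detected) "stroke detected" else "clean")

  tCrit <- range@vMax
  stroke <- check
  if (check@detected) {
    tCrit <- findCriticalThreshold(volA, brainA, range, ann$mask, cfg)
    note("critical threshold T = %.1f HU", tCrit)
    stroke <- extractStroke(volA, brainA, range, tCrit, ann$mask, cfg)
    seg <- subtractStroke(fmax, stroke, cfg)
    note("image difference removed %d stroke voxels", sum(stroke@paMask@mask))
    brainTpl <- binaryVolume(
      brainA@mask & !morphG(stroke@paMask@mask, cfg, cfg$strokeDilateR),
      spacing = brainA@spacing)
  } else {
    seg <- prelim
    brainTpl <- brainA
  }

  template <- buildTemplate(volA, brainTpl, range, cfg)
  seg2 <- applyTemplate(seg, template, cfg)
  note("template applied: %d -> %d voxels", sum(seg@mask), sum(seg2@mask))

  finalA <- refineMask(volA, seg2, range@vMax, cfg)
  excludedA <- binaryVolume(fmax@mask & !seg2@mask, spacing = fmax@spacing)
  final <- maskToInputGrid(finalA, al$transform, vol, range, cfg, excludedA)
  note("final mask: %d voxels", sum(final@mask))

  new("SegmentationResult", preliminary = prelim, tCritical = tCrit,
      stroke = stroke, template = template, finalAligned = finalA,
      final = final, range = range, plane = plane,
      transform = al$transform, log = logLines)
}
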