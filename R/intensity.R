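# Deterministic 1D 2-means (Lloyd) on intensity values.
# Init: class centres at the 10th and 90th percentile; iterate to
# convergence (tolerance in HU). Returns the class boundary (midpoint of
# the final centres) and the centres themselves.
kmeans1d2 <- function(values, tol = 1e-3, maxIter = 200L) {
  c1 <- unname(stats::quantile(values, 0.10))
  c2 <- unname(stats::quantile(values, 0.90))
  if (c1 == c2) {
    # strongly unbalanced classes: fall back to the extremes
    c1 <- min(values); c2 <- max(values)
    if (c1 == c2) stop("degenerate intensity distribution: constant values")
  }
  prevLow <- NULL
  for (i in seq_len(maxIter)) {
    s <- (c1 + c2) / 2
    low <- values <= s
    if (!any(low) || all(low))
      stop("degenerate intensity distribution: one empty class")
    # run to a fixed point of the assignment, not merely of the centres:
    # a centre drift below tol can still flip a boundary value
    if (!is.null(prevLow) && identical(low, prevLow)) break
    prevLow <- low
    c1 <- mean(values[low]); c2 <- mean(values[!low])
  }
  list(split = (c1 + c2) / 2, centers = c(c1, c2))
}

#' Candidate ventricle from 2-means brain stratification
#'
#' Applies 1D 2-means (K = 2) to the HU values of the brain voxels,
#' takes the lower-centre class, and returns its largest 26-connected 3D
#' component as the candidate ventricle. The clustering operates on
#' intensities only, not on spatial features.
#'
#' @param vol a \code{CTVolume} (typically MSL-aligned).
#' @param brain its brain mask.
#' @param cfg a \code{\link{segConfig}}.
#' @return A list: \code{candidate} (\code{BinaryVolume}, largest low
#'   component), \code{lowClass} (\code{BinaryVolume}, full lower class),
#'   \code{split} (HU class boundary), \code{centers}.
#' @export
clusterBrain <- function(vol, brain, cfg = segConfig()) {
  checkSameGeometry(vol, brain)
  if (!any(brain@mask)) stop("empty brain mask")
  km <- kmeans1d2(vol@voxels[brain@mask], tol = cfg$kmeansTol)
  low <- brain@mask & vol@voxels <= km$split
  if (!any(low)) stop("no low-intensity voxels inside the brain")
  lab <- labelComponents(low, cfg$connectivity)
  keep <- which.max(componentSizes(lab))
  list(candidate = binaryVolume(lab == keep, spacing = vol@spacing),
       lowClass = binaryVolume(low, spacing = vol@spacing),
       split = km$split, centers = km$centers)
}

#' Estimate the ventricular intensity range
#'
#' Builds the per-HU histogram of the candidate component and smooths it
#' with a 3-bin moving average. The mode is the histogram peak inside the
#' rough ventricular band (up to 12 HU, the domain-knowledge upper bound):
#' the candidate component also carries white matter, whose own peak near
#' 30 HU must not be mistaken for CSF. The slope is then tracked down from
#' the CSF mode: once the histogram has descended below half the peak, the
#' bins whose smoothed slope is non-negative or within 2\% of the peak
#' count form the valley floor between CSF and partial-volume/white
#' matter, and the critical intensity is the floor bin with the minimum
#' smoothed count (the histogram minimum method); tracking stops when the
#' counts rebound past twice the running minimum (the white-matter rise).
#' vMax is the critical intensity; vMin reflects the mode symmetrically
#' (clamped at 0); both are clamped into the [-5, 25] HU sanity band. When
#' no valley is found (e.g. a single spike) the domain defaults (1, 12) HU
#' are returned with \code{fallback = TRUE}.
#'
#' @param vol a \code{CTVolume}.
#' @param candidate candidate ventricle mask from \code{\link{clusterBrain}}.
#' @param cfg a \code{\link{segConfig}}.
#' @return An \linkS4class{IntensityRange}.
#' @export
estimateVentricleRange <- function(vol, candidate, cfg = segConfig()) {
  checkSameGeometry(vol, candidate)
  if (!any(candidate@mask)) stop("empty candidate mask")
  vals <- round(vol@voxels[candidate@mask])
  band <- cfg$sanityBandHu
  lo <- min(vals); hi <- max(band[2], max(vals)) + 2  # pad past the support
  hus <- lo:hi
  counts <- tabulate(vals - lo + 1L, nbins = length(hus))
  # 3-bin moving average (ends use the available neighbours)
  n <- length(counts)
  sm <- counts
  if (n >= 2) {
    ext <- c(counts[1], counts, counts[n])
    sm <- (ext[1:n] + ext[2:(n + 1)] + ext[3:(n + 2)]) / 3
  }
  histDf <- data.frame(hu = hus, count = counts, smoothed = sm)

  fallback <- function() new("IntensityRange",
    vMin = cfg$fallbackRangeHu[1], vMax = cfg$fallbackRangeHu[2],
    criticalIntensity = NA_real_, histogram = histDf, fallback = TRUE)

  roughIdx <- which(hus >= band[1] & hus <= cfg$fallbackRangeHu[2])
  if (length(roughIdx) == 0) return(fallback())
  modeIdx <- roughIdx[which.max(sm[roughIdx])]
  peak <- sm[modeIdx]
  mode <- hus[modeIdx]
  searchIdx <- seq_len(n - 1)
  searchIdx <- searchIdx[searchIdx > modeIdx & hus[searchIdx] <= band[2]]
  if (length(searchIdx) == 0) return(fallback())

  floorBins <- integer(0)
  valleyMin <- Inf
  descended <- FALSE
  for (i in searchIdx) {
    if (!descended && sm[i] <= 0.5 * peak) descended <- TRUE
    if (!descended) next
    # leaving the valley: counts rebound into the white-matter rise
    if (is.finite(valleyMin) && sm[i] > 2 * valleyMin) break
    slope <- sm[i + 1] - sm[i]
    onFloor <- slope >= 0 || abs(slope) < cfg$slopeTolFrac * peak
    # a genuine valley still carries counts; an exhausted histogram
    # (isolated spike) must fall through to the domain defaults
    if (sm[i] > 0 && onFloor) {
      floorBins <- c(floorBins, i)
      valleyMin <- min(valleyMin, sm[i])
    }
  }
  if (length(floorBins) == 0) return(fallback())
  # the valley floor is flat; a bare argmin would jitter with count noise
  # while the full floor run drifts with its entry/exit points. The stable
  # CSF/white-matter boundary is the midpoint of the bins lying within the
  # slope tolerance of the floor minimum.
  nearMin <- floorBins[sm[floorBins] <= valleyMin + cfg$slopeTolFrac * peak]
  critical <- hus[nearMin[ceiling(length(nearMin) / 2)]]

  vmax <- min(critical, band[2])
  vmin <- max(0, mode - (critical - mode))
  vmin <- max(vmin, band[1])
  if (vmin >= vmax) return(fallback())
  new("IntensityRange", vMin = vmin, vMax = vmax,
      criticalIntensity = critical, histogram = histDf, fallback = FALSE)
}
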