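#' Pipeline configuration
#'
#' All tunable constants of the segmentation pipeline in one place, with the
#' method's published defaults. Every run of \code{\link{segmentVentricle}}
#' records the effective configuration in its log.
#'
#' @param ... named overrides of the defaults listed below.
#' @return A named list with class \code{"segConfig"}.
#'
#' @details Defaults:
#' \describe{
#'   \item{skullHu (100)}{fixed bone threshold; voxels >= 100 HU are skull.}
#'   \item{smoothTaps (7), smoothSigma2 (2)}{vertical Gaussian filter for
#'     light-curve detection.}
#'   \item{laplacianMask (-0.5, 0, 1, 0, -0.5)}{zero-sum horizontal line
#'     detection mask.}
#'   \item{edgeSdMult (2.5)}{edge threshold = mean + 2.5 sd of the Laplacian
#'     response.}
#'   \item{minEdgeComponentVox (30)}{3D components below 30 voxels are
#'     removed from the edge map.}
#'   \item{edgeMaskErodeR (3)}{in-plane erosion of the brain mask before
#'     light-curve filtering; excludes the bright partial-volume rim of
#'     the inner skull table from the line detector.}
#'   \item{annulusWidthFrac (0.15)}{annulus width = 0.15 * Lmin.}
#'   \item{annulusAreaPx (20)}{per-slice overlap area (strictly) above which
#'     a stroke is declared.}
#'   \item{kmeansTol (1e-3)}{convergence tolerance (HU) of the 1D 2-means.}
#'   \item{slopeTolFrac (0.02)}{histogram-slope tolerance, as a fraction of
#'     the peak count, used by the valley search.}
#'   \item{sanityBandHu (-5, 25)}{clamp band for the estimated ventricular
#'     range.}
#'   \item{fallbackRangeHu (1, 12)}{domain-knowledge ventricular range used
#'     when no histogram valley is found.}
#'   \item{closingR (2)}{disk radius of the in-plane morphological closing.}
#'   \item{strokeDilateR (1)}{extra dilation of stroke masks before
#'     subtraction (removes lesion margins).}
#'   \item{templateDilateR (3)}{dilation of the adaptive template.}
#'   \item{templateMinVox (100)}{below this size the template threshold
#'     falls back from vMin to the band midpoint.}
#'   \item{appendagePx (20)}{out-of-template per-slice patches at or above
#'     this area are removed by the template step.}
#'   \item{calcificationMarginHu (30)}{voxels brighter than vMax + margin
#'     are removed as calcifications during refinement.}
#'   \item{specificityDomain ("brain")}{negative domain for specificity:
#'     "brain" restricts true negatives to the brain mask, "frame" uses the
#'     whole grid.}
#'   \item{connectivity (26)}{3D connectivity order for component labeling.}
#' }
#' @export
segConfig <- function(...) {
  cfg <- list(
    skullHu = 100,
    smoothTaps = 7L,
    smoothSigma2 = 2,
    laplacianMask = c(-0.5, 0, 1, 0, -0.5),
    edgeSdMult = 2.5,
    minEdgeComponentVox = 30L,
    edgeMaskErodeR = 3L,
    annulusWidthFrac = 0.15,
    annulusAreaPx = 20,
    kmeansTol = 1e-3,
    slopeTolFrac = 0.02,
    sanityBandHu = c(-5, 25),
    fallbackRangeHu = c(1, 12),
    closingR = 2L,
    strokeDilateR = 1L,
    templateDilateR = 3L,
    templateMinVox = 100L,
    appendagePx = 20,
    calcificationMarginHu = 30,
    specificityDomain = "brain",
    connectivity = 26L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  class(cfg) <- c("segConfig", "list")
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with any subset of the \code{\link{segConfig}} keys.
#' @return A \code{segConfig} list.
#' @export
readConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  vals <- yaml::read_yaml(path)
  do.call(segConfig, vals)
}

formatConfig <- function(cfg) {
  vapply(names(cfg), function(k)
    sprintf("%s=%s", k, paste(format(cfg[[k]]), collapse = ",")),
    character(1))
}
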