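#' Dice overlap coefficient
#'
#' 2 |Vs intersect Vr| / (|Vs| + |Vr|). When both masks are empty the
#' overlap is defined as 1 with a warning.
#'
#' @param seg,ref \code{BinaryVolume}s of equal shape.
#' @return Dice in [0, 1].
#' @export
diceCoefficient <- function(seg, ref) {
  checkSameGeometry(seg, ref)
  ns <- sum(seg@mask); nr <- sum(ref@mask)
  if (ns + nr == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(seg@mask & ref@mask) / (ns + nr)
}

#' Voxel-level sensitivity and specificity
#'
#' Sensitivity = TP / (TP + FN) and specificity = TN / (TN + FP), with
#' negatives counted inside \code{domain} only. The default evaluation
#' restricts the negative domain to the brain mask: counting the whole
#' 512 x 512 frame as negatives would inflate specificity to ~1 trivially.
#'
#' @param seg,ref \code{BinaryVolume}s.
#' @param domain negative-counting domain (must contain \code{ref}).
#' @return Named numeric: \code{sensitivity}, \code{specificity}.
#' @export
sensitivitySpecificity <- function(seg, ref, domain) {
  checkSameGeometry(seg, ref); checkSameGeometry(seg, domain)
  if (!any(ref@mask)) stop("empty reference: sensitivity undefined")
  if (any(ref@mask & !domain@mask))
    stop("domain must contain the reference mask")
  s <- seg@mask & domain@mask
  r <- ref@mask
  tp <- sum(s & r); fn <- sum(r & !s)
  fp <- sum(s & !r); tn <- sum(domain@mask & !s & !r)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

# Per-slice boundary point coordinates (x, y) of a 3D mask.
boundaryPointsBySlice <- function(mask) {
  b <- boundarySlices(mask)
  lapply(seq_len(dim(mask)[3]), function(z) {
    which(b[, , z], arr.ind = TRUE)
  })
}

#' Boundary RMSE between segmented and reference masks
#'
#' Extracts the per-slice boundary (mask voxels 8-adjacent to background
#' within the slice) of the segmentation; each boundary point is matched
#' to the closest reference boundary point in the same slice and the RMSE
#' of those distances is reported in mm using the in-plane spacing. The
#' measure is directional (segmented to reference), as defined. Slices
#' where the segmentation has a boundary but the reference does not are
#' skipped with a warning.
#'
#' @param seg,ref nonempty \code{BinaryVolume}s.
#' @param spacingMm in-plane pixel size (mm); defaults to the mask spacing.
#' @return RMSE in mm (attribute \code{skippedSlices} counts skipped
#'   slices).
#' @export
boundaryRMSE <- function(seg, ref, spacingMm = NULL) {
  checkSameGeometry(seg, ref)
  if (!any(seg@mask) || !any(ref@mask)) stop("both masks must be nonempty")
  if (is.null(spacingMm)) spacingMm <- seg@spacing[1]
  segB <- boundaryPointsBySlice(seg@mask)
  refB <- boundaryPointsBySlice(ref@mask)
  d2 <- numeric(0)
  skipped <- 0L
  for (z in seq_along(segB)) {
    ps <- segB[[z]]
    if (nrow(ps) == 0) next
    pr <- refB[[z]]
    if (nrow(pr) == 0) { skipped <- skipped + 1L; next }
    # squared distance from each seg point to its nearest ref point
    cross <- outer(ps[, 1], pr[, 1], "-")^2 + outer(ps[, 2], pr[, 2], "-")^2
    d2 <- c(d2, apply(cross, 1, min))
  }
  if (skipped > 0)
    warning(skipped, " slice(s) had a segmented boundary but no reference ",
            "boundary and were skipped")
  if (length(d2) == 0) stop("no comparable boundary points")
  structure(spacingMm * sqrt(mean(d2)), skippedSlices = skipped)
}

#' Segmentation reliability
#'
#' The fraction of cases segmented with Dice strictly greater than d.
#'
#' @param dices numeric vector of per-case Dice values.
#' @param d threshold in [0, 1].
#' @return Fraction in [0, 1].
#' @export
reliability <- function(dices, d) {
  stopifnot(length(dices) > 0, d >= 0, d <= 1)
  mean(dices > d)
}

#' Pearson correlation of paired volumes
#'
#' The product-moment correlation of segmented versus reference volumes,
#' computed directly from its sum form
#' \deqn{R = \frac{n\sum V_s V_r - \sum V_s \sum V_r}{\sqrt{n\sum V_s^2 -
#'   (\sum V_s)^2}\sqrt{n\sum V_r^2 - (\sum V_r)^2}}.}
#'
#' @param volsSeg,volsRef equal-length numeric vectors (length >= 3) with
#'   nonzero variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
volumeCorrelation <- function(volsSeg, volsRef) {
  n <- length(volsSeg)
  stopifnot(n == length(volsRef), n >= 3)
  num <- n * sum(volsSeg * volsRef) - sum(volsSeg) * sum(volsRef)
  den1 <- n * sum(volsSeg^2) - sum(volsSeg)^2
  den2 <- n * sum(volsRef^2) - sum(volsRef)^2
  if (den1 <= 0 || den2 <= 0) stop("zero variance in volumes")
  num / sqrt(den1 * den2)
}

#' Evaluate one segmentation against its reference
#'
#' @param seg predicted ventricle mask.
#' @param ref reference ventricle mask.
#' @param domain negative domain for specificity (typically the brain
#'   mask); when NULL the whole frame is used.
#' @param id case identifier.
#' @return One-row data.frame: id, dice, sensitivity, specificity, rmseMm,
#'   volSegMl, volRefMl.
#' @export
evaluateSegmentation <- function(seg, ref, domain = NULL, id = NA) {
  if (is.null(domain))
    domain <- binaryVolume(array(TRUE, dim(seg@mask)), spacing = seg@spacing)
  ss <- sensitivitySpecificity(seg, ref, domain)
  vx <- prod(seg@spacing) / 1000
  data.frame(id = id,
             dice = diceCoefficient(seg, ref),
             sensitivity = unname(ss["sensitivity"]),
             specificity = unname(ss["specificity"]),
             rmseMm = as.numeric(boundaryRMSE(seg, ref)),
             volSegMl = sum(seg@mask) * vx,
             volRefMl = sum(ref@mask) * vx)
}

#' Summarise a suite of evaluations
#'
#' Mean, SD (n - 1 denominator), min and max for each metric; the
#' reliability curve sampled on d in [0.5, 1] with step 0.01; and the
#' volume correlation. A single-case suite reports SD 0 with a flag.
#'
#' @param reports data.frame of rows from
#'   \code{\link{evaluateSegmentation}}.
#' @return A list: \code{summary} (data.frame metric x Mean/SD/Min/Max),
#'   \code{reliability} (data.frame d, R), \code{volumeCorrelation},
#'   \code{sdDefined}.
#' @export
summarizeSuite <- function(reports) {
  stopifnot(nrow(reports) >= 1)
  metrics <- c("dice", "sensitivity", "specificity", "rmseMm")
  single <- nrow(reports) == 1
  summ <- do.call(rbind, lapply(metrics, function(m) {
    v <- reports[[m]]
    data.frame(metric = m, mean = mean(v),
               sd = if (single) 0 else stats::sd(v),
               min = min(v), max = max(v))
  }))
  dGrid <- seq(0.5, 1, by = 0.01)
  rel <- data.frame(d = dGrid,
                    R = vapply(dGrid, function(d)
                      reliability(reports$dice, d), numeric(1)))
  vc <- if (nrow(reports) >= 3)
    volumeCorrelation(reports$volSegMl, reports$volRefMl) else NA_real_
  list(summary = summ, reliability = rel, volumeCorrelation = vc,
       sdDefined = !single)
}
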