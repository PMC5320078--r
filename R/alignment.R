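#' Strip the skull from a head CT
#'
#' Bone is everything at or above the fixed 100 HU threshold. The brain is
#' the largest 3D region enclosed by bone: per slice the bone mask is
#' hole-filled, bone itself subtracted, and the largest 26-connected 3D
#' component of the remainder kept, which excludes the background outside
#' the skull.
#'
#' @param vol a \code{CTVolume} in HU.
#' @param cfg a \code{\link{segConfig}}.
#' @return A \linkS4class{BinaryVolume} brain mask.
#' @export
stripSkull <- function(vol, cfg = segConfig()) {
  bone <- vol@voxels >= cfg$skullHu
  if (!any(bone)) stop("no skull found: no voxel at or above ",
                       cfg$skullHu, " HU")
  filled <- fillHolesSlices(bone)
  inside <- filled & !bone
  if (!any(inside)) stop("no region enclosed by the skull")
  lab <- labelComponents(inside, cfg$connectivity)
  sizes <- componentSizes(lab)
  keep <- which.max(sizes)
  binaryVolume(lab == keep, spacing = vol@spacing)
}

#' Define the light-curve detection ROI
#'
#' Takes the slice-wise smallest minimum bounding rectangle of the brain
#' over the whole scan; the ROI is half that rectangle's width, centered on
#' the rectangle's vertical midline, at full image height.
#'
#' @param brain a \code{BinaryVolume} brain mask.
#' @return A list with \code{xRange} (columns), \code{yRange} (full height),
#'   \code{rect} (x1, x2, y1, y2 of the selected rectangle) and
#'   \code{slice} (index of the slice supplying it).
#' @export
defineROI <- function(brain) {
  m <- brain@mask
  nz <- dim(m)[3]
  best <- NULL
  for (z in seq_len(nz)) {
    sl <- m[, , z]
    if (!any(sl)) next
    xs <- range(which(rowSums(sl) > 0))
    ys <- range(which(colSums(sl) > 0))
    area <- diff(xs + c(0, 1)) * diff(ys + c(0, 1))
    if (is.null(best) || area < best$area)
      best <- list(area = area, rect = c(xs, ys), slice = z)
  }
  if (is.null(best)) stop("empty brain mask")
  x1 <- best$rect[1]; x2 <- best$rect[2]
  w <- x2 - x1 + 1
  center <- (x1 + x2) / 2
  roiW <- round(w / 2)
  lo <- round(center - roiW / 2 + 0.5)
  hi <- lo + roiW - 1
  lo <- max(1, lo); hi <- min(dim(m)[1], hi)
  list(xRange = c(lo, hi), yRange = c(1, dim(m)[2]),
       rect = best$rect, slice = best$slice)
}

#' Vertical Gaussian smoothing of a slice
#'
#' One-dimensional 7-tap Gaussian (variance 2) applied along the vertical
#' (y) axis only, kernel normalised to sum 1, reflective boundary. Preserves
#' the horizontal edge profile of near-vertical light curves.
#'
#' @param img 2D numeric matrix (indexed [x, y]).
#' @param cfg a \code{\link{segConfig}}.
#' @return Filtered matrix of the same size.
#' @export
smoothVertical <- function(img, cfg = segConfig()) {
  convolveAxisReflect(img, gaussianTaps(cfg$smoothTaps, cfg$smoothSigma2),
                      margin = 2)
}

#' Horizontal Laplacian line response
#'
#' Correlation with the zero-sum horizontal line-detection mask
#' (-0.5, 0, 1, 0, -0.5) along x, reflective boundary. A bright 1-px
#' vertical line of height h yields response h on the line and -h/2 two
#' pixels to either side.
#'
#' @param img filtered slice matrix.
#' @param cfg a \code{\link{segConfig}}.
#' @return Response matrix.
#' @export
laplacianResponse <- function(img, cfg = segConfig()) {
  convolveAxisReflect(img, rev(cfg$laplacianMask), margin = 1)
}

#' Adaptive edge thresholding of a Laplacian response
#'
#' Threshold t = mean + 2.5 sd of the response over the slice ROI; the edge
#' map is \code{response > t}. A zero-variance response gives an empty map.
#'
#' @param resp response matrix for one slice.
#' @param cfg a \code{\link{segConfig}}.
#' @return Logical matrix.
#' @export
thresholdEdges <- function(resp, cfg = segConfig()) {
  s <- stats::sd(resp)
  if (!is.finite(s) || s == 0) return(array(FALSE, dim(resp)))
  resp > mean(resp) + cfg$edgeSdMult * s
}

#' Remove small 3D components from a stacked edge map
#'
#' 26-connected 3D components with fewer than 30 voxels are discarded.
#'
#' @param edges 3D logical array of per-slice edge masks.
#' @param spacing voxel spacing (mm) carried to the output.
#' @param cfg a \code{\link{segConfig}}.
#' @return A list: \code{mask} (\code{BinaryVolume} of surviving edges) and
#'   \code{points} (matrix of voxel indices x, y, z). Both empty when every
#'   component is below threshold (the caller falls back to the brain
#'   bounding-box midline).
#' @export
denoiseEdges3D <- function(edges, spacing = c(0.426, 0.426, 5),
                           cfg = segConfig()) {
  lab <- labelComponents(edges, cfg$connectivity)
  sizes <- componentSizes(lab)
  keepIds <- which(sizes >= cfg$minEdgeComponentVox)
  kept <- array(lab %in% keepIds & lab > 0, dim(edges))
  pts <- which(kept, arr.ind = TRUE)
  colnames(pts) <- c("x", "y", "z")
  list(mask = binaryVolume(kept, spacing = spacing), points = pts)
}

#' Detect falx-cerebri light curves across a scan
#'
#' Runs the per-slice detection chain (ROI restriction, vertical Gaussian,
#' horizontal Laplacian, mean + 2.5 sd threshold) on every slice and cleans
#' the stacked edge maps with the 3D 30-voxel component filter. Non-brain
#' pixels are replaced by the slice's mean brain intensity before
#' filtering, so the skull-stripped mask edge itself produces no line
#' response.
#'
#' @param vol a \code{CTVolume}.
#' @param brain its brain mask.
#' @param cfg a \code{\link{segConfig}}.
#' @return A list: \code{points} (x, y, z edge voxels in full-image
#'   coordinates), \code{mask} (edge \code{BinaryVolume}), \code{roi}.
#' @export
detectLightCurves <- function(vol, brain, cfg = segConfig()) {
  checkSameGeometry(vol, brain)
  roi <- defineROI(brain)
  d <- dim(vol@voxels)
  xs <- roi$xRange[1]:roi$xRange[2]
  edges <- array(FALSE, d)
  # erode the brain a little so the bright partial-volume rim of the
  # inner skull table does not masquerade as a light curve
  core <- morphErodeSlices(brain@mask, cfg$edgeMaskErodeR)
  for (z in seq_len(d[3])) {
    sl <- vol@voxels[, , z]
    b <- core[, , z]
    sl[!b] <- if (any(b)) mean(sl[b]) else 0
    sub <- sl[xs, , drop = FALSE]
    resp <- laplacianResponse(smoothVertical(sub, cfg), cfg)
    edges[xs, , z] <- thresholdEdges(resp, cfg)
  }
  den <- denoiseEdges3D(edges, vol@spacing, cfg)
  list(points = den$points, mask = den$mask, roi = roi)
}

#' Fit the 3D midsagittal plane
#'
#' Least-squares fit of the plane x = a*y + b*z + c through the edge points
#' (normal equations, closed form). The x = f(y, z) parametrisation is
#' well-conditioned for near-vertical sagittal planes. When the points span
#' a single slice the z term is dropped (b = 0); when they span a single
#' line the plane degenerates to the vertical plane through their mean x.
#'
#' @param points matrix/data.frame with columns x, y, z (voxel indices).
#' @return A \linkS4class{MidsagittalPlane}, or NULL when fewer than 3
#'   points are supplied or the fitted line is too far from vertical
#'   (fallback signal for the caller).
#' @export
fitMidsagittalPlane <- function(points) {
  pts <- as.matrix(points)
  if (is.null(dim(pts)) || nrow(pts) < 3) return(NULL)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  hasY <- length(unique(y)) > 1
  hasZ <- length(unique(z)) > 1
  if (hasY && hasZ) {
    fit <- stats::lm.fit(cbind(y = y, z = z, 1), x)
    if (any(is.na(fit$coefficients))) {
      hasZ <- FALSE   # y and z collinear; refit without z
    } else {
      cf <- fit$coefficients
      res <- sqrt(mean(fit$residuals^2))
      return(tryCatch(
        new("MidsagittalPlane", a = unname(cf[1]), b = unname(cf[2]),
            c = unname(cf[3]), residualRMS = res, nPoints = nrow(pts)),
        error = function(e) NULL))
    }
  }
  if (hasY) {
    fit <- stats::lm.fit(cbind(y = y, 1), x)
    cf <- fit$coefficients
    res <- sqrt(mean(fit$residuals^2))
    return(tryCatch(
      new("MidsagittalPlane", a = unname(cf[1]), b = 0, c = unname(cf[2]),
          residualRMS = res, nPoints = nrow(pts)),
      error = function(e) NULL))
  }
  new("MidsagittalPlane", a = 0, b = 0, c = mean(x),
      residualRMS = stats::sd(x), nPoints = nrow(pts))
}

#' Fallback midsagittal plane
#'
#' The vertical plane through the scan-wide brain bounding-box centre,
#' used when too few falx edge points survive (the falx shows on only
#' ~30\% of slices and may be absent from a scan).
#'
#' @param brain a \code{BinaryVolume}.
#' @return A \linkS4class{MidsagittalPlane} with \code{fallback = TRUE}.
#' @export
fallbackPlane <- function(brain) {
  any2d <- apply(brain@mask, 1, any)
  if (!any(any2d)) stop("empty brain mask")
  xs <- range(which(any2d))
  new("MidsagittalPlane", a = 0, b = 0, c = mean(xs), residualRMS = NA_real_,
      nPoints = 0, fallback = TRUE)
}

#' Midsagittal line of one slice
#'
#' The intersection of the fitted plane with slice z: the in-slice line
#' x = a*y + (b*z + c), at angle atan(a) to the vertical.
#'
#' @param plane a \code{MidsagittalPlane}.
#' @param z slice index.
#' @return A list with \code{a} (slope dx/dy), \code{intercept} (x at
#'   y = 0) and \code{theta} (radians from vertical).
#' @export
mslForSlice <- function(plane, z) {
  list(a = plane@a, intercept = plane@b * z + plane@c,
       theta = atan(plane@a))
}

# Build the per-slice aligning transform from a fitted plane.
buildTransform <- function(plane, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ctr <- c((nx + 1) / 2, (ny + 1) / 2)
  thetaL <- atan(plane@a)
  shiftX <- numeric(nz)
  for (z in seq_len(nz)) {
    msl <- mslForSlice(plane, z)
    # line point at the centre row, pushed through the aligning rotation
    L <- c(msl$a * ctr[2] + msl$intercept, ctr[2])
    rot <- affineMapXY(L[1], L[2], thetaL, ctr)
    shiftX[z] <- ctr[1] - rot$x
  }
  new("AlignmentTransform", theta = thetaL, center = ctr, shiftX = shiftX,
      dims = as.integer(dims))
}

#' Align a volume to its midsagittal plane
#'
#' Each slice is rotated by the MSL inclination about the image centre
#' (proper rotation matrix) and translated so the midsagittal line maps
#' onto the vertical centerline. HU values are interpolated bilinearly;
#' out-of-frame voxels are filled with -1000 HU (air).
#'
#' @param vol a \code{CTVolume}.
#' @param plane a fitted \code{MidsagittalPlane}.
#' @return A list with \code{volume} (aligned \code{CTVolume}) and
#'   \code{transform} (\linkS4class{AlignmentTransform}).
#' @export
alignVolume <- function(vol, plane) {
  d <- dim(vol@voxels)
  tr <- buildTransform(plane, d)
  out <- vol@voxels
  for (z in seq_len(d[3])) {
    out[, , z] <- resampleSlice(vol@voxels[, , z], -tr@theta, tr@center,
                                pre = c(tr@shiftX[z], 0),
                                interp = "bilinear", fill = -1000)
  }
  list(volume = ctVolume(out, vol@spacing), transform = tr)
}

#' Apply an alignment transform to a mask
#'
#' Nearest-neighbour resampling of a binary mask into aligned space.
#'
#' @param mask a \code{BinaryVolume} on the input grid.
#' @param transform an \code{AlignmentTransform}.
#' @return The aligned \code{BinaryVolume}.
#' @export
applyTransformMask <- function(mask, transform) {
  d <- dim(mask@mask)
  out <- mask@mask
  for (z in seq_len(d[3])) {
    out[, , z] <- resampleSlice(mask@mask[, , z], -transform@theta,
                                transform@center,
                                pre = c(transform@shiftX[z], 0),
                                interp = "nearest", fill = FALSE) > 0.5
  }
  binaryVolume(out, spacing = mask@spacing)
}

#' Resample an aligned-space mask back to the input grid
#'
#' Inverse of the aligning transform. The binary mask is sampled with
#' bilinear interpolation and re-binarised at 0.5, which keeps the decision
#' boundary at sub-voxel accuracy instead of introducing nearest-neighbour
#' jitter.
#'
#' @param mask a \code{BinaryVolume} in aligned space.
#' @param transform the \code{AlignmentTransform} used for alignment.
#' @return The mask on the input grid.
#' @export
resampleMaskToInput <- function(mask, transform) {
  d <- dim(mask@mask)
  out <- mask@mask
  for (z in seq_len(d[3])) {
    out[, , z] <- resampleSlice(mask@mask[, , z] * 1, transform@theta,
                                transform@center,
                                post = c(transform@shiftX[z], 0),
                                interp = "bilinear", fill = 0) >= 0.5
  }
  binaryVolume(out, spacing = mask@spacing)
}
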