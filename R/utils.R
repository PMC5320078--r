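#' @useDynLib ventriseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Construct a CTVolume
#'
#' @param voxels 3D numeric array in HU.
#' @param spacing numeric(3) spacing (dx, dy, dz) in mm.
#' @return A \code{CTVolume}.
#' @export
ctVolume <- function(voxels, spacing = c(0.426, 0.426, 5)) {
  storage.mode(voxels) <- "double"
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing))
}

#' Construct a BinaryVolume
#'
#' @param mask 3D logical (or coercible) array.
#' @param ref a \code{CTVolume} or \code{BinaryVolume} supplying geometry, or
#'   NULL when \code{spacing} is given.
#' @param spacing numeric(3) spacing in mm, used when \code{ref} is NULL.
#' @return A \code{BinaryVolume}.
#' @export
binaryVolume <- function(mask, ref = NULL, spacing = NULL) {
  m <- array(as.logical(mask), dim = dim(mask))
  sp <- if (!is.null(ref)) ref@spacing else spacing
  if (is.null(sp)) stop("either ref or spacing must be supplied")
  if (!is.null(ref)) {
    rd <- if (is(ref, "CTVolume")) dim(ref@voxels) else dim(ref@mask)
    if (!identical(dim(m), rd))
      stop("mask shape does not match the reference volume")
  }
  new("BinaryVolume", mask = m, spacing = as.numeric(sp))
}

checkSameGeometry <- function(a, b) {
  da <- if (is(a, "CTVolume")) dim(a@voxels) else dim(a@mask)
  db <- if (is(b, "CTVolume")) dim(b@voxels) else dim(b@mask)
  if (!identical(da, db)) stop("volume shapes do not match")
  invisible(TRUE)
}

emptyMaskLike <- function(ref) {
  d <- if (is(ref, "CTVolume")) dim(ref@voxels) else dim(ref@mask)
  binaryVolume(array(FALSE, d), spacing = ref@spacing)
}

## ---- connected components (Rcpp backend) -----------------------------------

labelComponents <- function(mask, connectivity = 26) {
  lab <- .label_components(as.logical(mask), as.integer(dim(mask)),
                           as.integer(connectivity))
  structure(array(lab, dim = dim(mask)),
            max_label = attr(lab, "max_label"))
}

componentSizes <- function(labels) {
  k <- attr(labels, "max_label")
  if (is.null(k)) k <- max(labels)
  if (k == 0) integer(0) else tabulate(labels[labels > 0L], nbins = k)
}

## ---- 1D convolution with reflective boundary -------------------------------

# Correlate a matrix with a centred odd-length 1D kernel along one array
# margin (1 = first index / image x, 2 = second index / image y); boundary
# handled by reflection (edge sample not repeated). Slice matrices in this
# package are indexed [x, y].
convolveAxisReflect <- function(mat, kernel, margin) {
  k <- length(kernel)
  stopifnot(k %% 2 == 1, margin %in% 1:2)
  h <- (k - 1) / 2
  if (margin == 2) return(t(convolveAxisReflect(t(mat), kernel, 1)))
  n <- nrow(mat)
  if (n == 1) return(mat * sum(kernel))
  padTop <- mat[pmin(h:1 + 1, n), , drop = FALSE]      # reflect (no repeat of edge)
  padBot <- mat[pmax(n - (1:h), 1), , drop = FALSE]
  ext <- rbind(padTop, mat, padBot)
  out <- matrix(0, n, ncol(mat))
  for (j in seq_len(k)) out <- out + kernel[j] * ext[(j - 1) + seq_len(n), , drop = FALSE]
  out
}

# 7-tap discrete Gaussian, variance sigma2, normalised to sum 1.
gaussianTaps <- function(ntap = 7, sigma2 = 2) {
  h <- (ntap - 1) / 2
  w <- exp(-((-h:h)^2) / (2 * sigma2))
  w / sum(w)
}

## ---- rigid in-plane resampling ---------------------------------------------

# Affine point map p = center + R(theta) (q - center - pre) + post for
# in-plane coordinates; used both by the phantom generator (forward rigid
# motion) and the alignment transform (and its inverse).
affineMapXY <- function(xq, yq, theta, center, pre = c(0, 0), post = c(0, 0)) {
  ct <- cos(theta); st <- sin(theta)
  ux <- xq - center[1] - pre[1]
  uy <- yq - center[2] - pre[2]
  list(x = center[1] + ct * ux - st * uy + post[1],
       y = center[2] + st * ux + ct * uy + post[2])
}

bilinearSample <- function(mat, xs, ys, fill) {
  nx <- nrow(mat); ny <- ncol(mat)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  inside <- x0 >= 1 & x0 + 1 <= nx & y0 >= 1 & y0 + 1 <= ny
  out <- rep(fill, length(xs))
  if (any(inside)) {
    x0i <- x0[inside]; y0i <- y0[inside]
    fxi <- fx[inside]; fyi <- fy[inside]
    i00 <- cbind(x0i, y0i); i10 <- cbind(x0i + 1, y0i)
    i01 <- cbind(x0i, y0i + 1); i11 <- cbind(x0i + 1, y0i + 1)
    out[inside] <- mat[i00] * (1 - fxi) * (1 - fyi) +
      mat[i10] * fxi * (1 - fyi) +
      mat[i01] * (1 - fxi) * fyi +
      mat[i11] * fxi * fyi
  }
  out
}

nearestSample <- function(mat, xs, ys, fill) {
  nx <- nrow(mat); ny <- ncol(mat)
  xi <- round(xs); yi <- round(ys)
  inside <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
  out <- rep(fill, length(xs))
  if (any(inside)) out[inside] <- mat[cbind(xi[inside], yi[inside])]
  out
}

# Resample one slice under the point map q -> p (target to source).
resampleSlice <- function(mat, theta, center, pre = c(0, 0), post = c(0, 0),
                          interp = c("bilinear", "nearest"), fill = -1000) {
  interp <- match.arg(interp)
  nx <- nrow(mat); ny <- ncol(mat)
  xq <- rep(seq_len(nx), times = ny)
  yq <- rep(seq_len(ny), each = nx)
  p <- affineMapXY(xq, yq, theta, center, pre, post)
  v <- if (interp == "bilinear") bilinearSample(mat, p$x, p$y, fill)
       else nearestSample(mat, p$x, p$y, fill)
  matrix(v, nx, ny)
}

## ---- per-slice morphology (EBImage backend) --------------------------------

discBrush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")

applySlices <- function(arr, fun) {
  out <- arr
  for (z in seq_len(dim(arr)[3])) out[, , z] <- fun(arr[, , z])
  out
}

morphCloseSlices <- function(mask, r) {
  if (r <= 0) return(mask)
  b <- discBrush(r)
  m <- applySlices(mask * 1, function(s) EBImage::closing(s, b))
  array(m > 0.5, dim(mask))
}

morphErodeSlices <- function(mask, r) {
  if (r <= 0) return(mask)
  b <- discBrush(r)
  m <- applySlices(mask * 1, function(s) EBImage::erode(s, b))
  array(m > 0.5, dim(mask))
}

morphDilateSlices <- function(mask, r) {
  if (r <= 0) return(mask)
  b <- discBrush(r)
  m <- applySlices(mask * 1, function(s) EBImage::dilate(s, b))
  array(m > 0.5, dim(mask))
}

fillHolesSlices <- function(mask) {
  m <- applySlices(mask * 1, function(s) EBImage::fillHull(s))
  array(m > 0.5, dim(mask))
}

# In-slice Euclidean distance to background; used for the brain-edge annulus.
distanceToBackgroundSlices <- function(mask) {
  applySlices(mask * 1, function(s) {
    if (!any(s > 0)) return(s)
    EBImage::distmap(s)
  })
}

# Boundary voxels: mask voxels 8-adjacent to background within their slice.
boundarySlices <- function(mask) {
  applySlices(mask, function(s) {
    if (!any(s)) return(s)
    n <- nrow(s); m <- ncol(s)
    er <- s
    padded <- matrix(FALSE, n + 2, m + 2)
    padded[2:(n + 1), 2:(m + 1)] <- s
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      er <- er & padded[2:(n + 1) + dx, 2:(m + 1) + dy]
    }
    s & !er
  })
}

# In-plane Gaussian blur (separable, reflective boundary).
blurSlices <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  h <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-h:h)^2) / (2 * sigma^2)); w <- w / sum(w)
  applySlices(arr, function(s)
    convolveAxisReflect(convolveAxisReflect(s, w, 1), w, 2))
}
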