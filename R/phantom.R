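#' Create a phantom specification
#'
#' Builds and validates a \linkS4class{PhantomSpec}. Defaults reproduce the
#' conditions the segmentation pipeline assumes: 0.426 mm pixels, 5 mm
#' slices, a skull plateau at 1000 HU, ventricular CSF at 1-12 HU inside
#' periventricular white matter (25-38 HU) and gray matter (35-60 HU), a
#' faint (+8 HU) falx light curve on about 30\% of slices, in-plane Gaussian
#' partial-volume blur of 1 px and 3 HU additive noise. The default grid is
#' 256 x 256 x 14; in-plane geometry scales with \code{min(nx, ny)/256}, so
#' a full 512 x 512 acquisition matrix can be requested via
#' \code{gridShape}.
#'
#' @param gridShape integer(3) grid (nx, ny, nz).
#' @param pixelMm,sliceMm voxel spacing in mm.
#' @param skullHu skull value (HU).
#' @param ventricleHuRange,whiteHuRange,grayHuRange tissue HU ranges.
#' @param falxProbPerSlice per-slice Bernoulli probability of a falx line.
#' @param falxContrastHu additive falx brightness (HU).
#' @param tiltDeg head rotation in degrees, within [-15, 15].
#' @param shiftPx numeric(2) in-plane translation (x, y) in pixels.
#' @param strokeSpec list of lesion descriptors; each a list with
#'   \code{placement} ("edge" or "periventricular"), \code{radiusMm},
#'   \code{huRange}, and optional \code{angleRad} (edge) or \code{side}
#'   (periventricular, -1/+1) controlling where the lesion is seeded.
#' @param noiseSdHu additive Gaussian noise SD (HU).
#' @param psfSigmaPx in-plane PSF sigma (px).
#' @param ventricleWidthScale scales the in-plane ventricle calibre
#'   (lobe offset, lobe width, slit width) to emulate anatomical
#'   ventricle-size variation; volume scales roughly linearly.
#' @param seed integer seed; the same seed reproduces the phantom
#'   bit-identically.
#' @return A \code{PhantomSpec}.
#' @export
phantomSpec <- function(gridShape = c(256L, 256L, 14L),
                        pixelMm = 0.426, sliceMm = 5,
                        skullHu = 1000,
                        ventricleHuRange = c(1, 12),
                        whiteHuRange = c(25, 38),
                        grayHuRange = c(35, 60),
                        falxProbPerSlice = 0.30,
                        falxContrastHu = 8,
                        tiltDeg = 0,
                        shiftPx = c(0, 0),
                        strokeSpec = list(),
                        noiseSdHu = 3,
                        psfSigmaPx = 1,
                        ventricleWidthScale = 1,
                        seed = 1L) {
  new("PhantomSpec",
      gridShape = as.integer(gridShape), pixelMm = pixelMm, sliceMm = sliceMm,
      skullHu = skullHu, ventricleHuRange = as.numeric(ventricleHuRange),
      whiteHuRange = as.numeric(whiteHuRange),
      grayHuRange = as.numeric(grayHuRange),
      falxProbPerSlice = falxProbPerSlice, falxContrastHu = falxContrastHu,
      tiltDeg = tiltDeg, shiftPx = as.numeric(shiftPx),
      strokeSpec = strokeSpec, noiseSdHu = noiseSdHu,
      psfSigmaPx = psfSigmaPx, ventricleWidthScale = ventricleWidthScale,
      seed = as.integer(seed))
}

# In-plane geometry of the procedural head, shared by all builders.
# All lengths in pixels of the generated grid (scale sc = min(nx,ny)/256).
# The head outline is a superellipse (exponent 2.7): axial head sections are
# flatter than an ellipse, and a near-horizontal vertex boundary keeps the
# skull-stripped brain edge silent under a horizontal line detector.
phantomGeometry <- function(spec) {
  g <- spec@gridShape
  nx <- g[1]; ny <- g[2]; nz <- g[3]
  sc <- min(nx, ny) / 256
  list(nx = nx, ny = ny, nz = nz, sc = sc,
       cx = (nx + 1) / 2, cy = (ny + 1) / 2, zc = (nz + 1) / 2,
       ax = 0.40 * nx, ay = 0.46 * ny,      # outer skull semi-axes
       p = 2.7,                             # superellipse exponent
       ringPx = max(2, round(3 * sc)),      # skull ring thickness
       whiteFrac = c(0.58, 0.60),           # white-matter region fraction
       ventY = c(-0.25, 0.35),              # lobe extent, fraction of ay
       lobeOffsPx = 18 * sc * spec@ventricleWidthScale,
       lobeHalfPx = 16 * sc * spec@ventricleWidthScale,
       slitY = c(-0.02, 0.22),              # 3rd-ventricle slit extent
       slitHalfPx = 3 * sc * spec@ventricleWidthScale,
       fissureAntY = c(-0.85, -0.28),       # interhemispheric fissure,
       fissurePostY = c(0.40, 0.85),        # fraction of ay
       fissureHalfPx = 2 * sc,
       falxHalfPx = max(0.5, 1 * sc))       # falx fold inside the fissure
}

# Per-slice head scale: slightly smaller at the top/bottom of the stack.
headScale <- function(z, zc, nz) sqrt(1 - 0.25 * ((2 * (z - zc)) / max(nz - 1, 1))^2)

# Ventricle scale across slices: lobes span the central third of the stack.
ventricleScale <- function(z, zc, nz) {
  v <- (z - zc) / (nz / 6 + 0.5)
  ifelse(abs(v) < 1, sqrt(1 - v^2), 0)
}

# Ideal (untransformed) tissue label masks for one slice.
# Returns logical matrices: skull, brain, white, ventricle, fissure.
phantomSliceMasks <- function(geom, z, X, Y) {
  s <- headScale(z, geom$zc, geom$nz)
  p <- geom$p
  ellipse <- function(sa, sb)
    (abs(X - geom$cx) / sa)^p + (abs(Y - geom$cy) / sb)^p <= 1
  outer_ <- ellipse(geom$ax * s, geom$ay * s)
  inner <- ellipse(geom$ax * s - geom$ringPx, geom$ay * s - geom$ringPx)
  # white matter: feathered superellipse region -- the white/gray
  # interface in CT is a gradual, low-contrast transition, not a step
  rw <- (abs(X - geom$cx) / (geom$ax * s * geom$whiteFrac[1]))^p +
    (abs(Y - geom$cy) / (geom$ay * s * geom$whiteFrac[2]))^p
  white <- rw <= 1
  whiteBlend <- pmax(0, pmin(1, (1.15 - rw) / 0.35))

  sv <- ventricleScale(z, geom$zc, geom$nz)
  vent <- matrix(FALSE, geom$nx, geom$ny)
  dxm <- abs(X - geom$cx)
  if (sv > 0) {
    y0 <- geom$cy + geom$ventY[1] * geom$ay
    y1 <- geom$cy + geom$ventY[2] * geom$ay
    u <- (Y - y0) / (y1 - y0)
    inBand <- u >= 0 & u <= 1
    # lateral ventricle bodies run parasagittal: straight bars parallel to
    # the midline, tapered at the frontal and occipital horns
    trap <- pmax(0, pmin(1, pmin(u, 1 - u) / 0.15))
    offs <- geom$lobeOffsPx
    halfw <- geom$lobeHalfPx * trap * sv
    lobes <- inBand & halfw > 0 & dxm >= offs - halfw & dxm <= offs + halfw
    slit <- matrix(FALSE, geom$nx, geom$ny)
    if (abs(z - geom$zc) <= geom$nz / 9) {
      sy0 <- geom$cy + geom$slitY[1] * geom$ay
      sy1 <- geom$cy + geom$slitY[2] * geom$ay
      slit <- dxm <= geom$slitHalfPx & Y >= sy0 & Y <= sy1
    }
    vent <- (lobes | slit) & white
  }

  # interhemispheric fissure: a narrow CSF groove along the midline,
  # anterior and posterior to the ventricles, on every slice
  dxm <- abs(X - geom$cx)
  antY <- geom$cy + geom$fissureAntY * geom$ay * s
  postY <- geom$cy + geom$fissurePostY * geom$ay * s
  fissure <- dxm <= geom$fissureHalfPx &
    ((Y >= antY[1] & Y <= antY[2]) | (Y >= postY[1] & Y <= postY[2]))
  fissure <- fissure & inner & !vent

  list(skull = outer_ & !inner, brain = inner, white = white & inner,
       whiteBlend = whiteBlend, ventricle = vent, fissure = fissure,
       headScaleZ = s)
}

# Falx cerebri fold: the bright line inside the fissure (ideal space).
phantomFalxMask <- function(geom, z, X, Y) {
  s <- headScale(z, geom$zc, geom$nz)
  antY <- geom$cy + geom$fissureAntY * geom$ay * s
  postY <- geom$cy + geom$fissurePostY * geom$ay * s
  abs(X - geom$cx) <= geom$falxHalfPx &
    ((Y >= antY[1] & Y <= antY[2]) | (Y >= postY[1] & Y <= postY[2]))
}

# Seed a lesion sphere (mm metric) and clip it to the brain while keeping
# it off the ventricle. Returns a logical 3D array.
placeLesion <- function(lesion, geom, spec, brain, ventricle) {
  rMm <- lesion$radiusMm
  rPx <- rMm / spec@pixelMm
  if (identical(lesion$placement, "edge")) {
    ang <- if (!is.null(lesion$angleRad)) lesion$angleRad else runif(1, 0, 2 * pi)
    depth <- if (!is.null(lesion$depthFrac)) lesion$depthFrac else runif(1, 0.04, 0.12)
    zc0 <- round(geom$zc + runif(1, -2, 2))
    s <- headScale(zc0, geom$zc, geom$nz)
    cxL <- geom$cx + (geom$ax * s - geom$ringPx) * (1 - depth) * cos(ang)
    cyL <- geom$cy + (geom$ay * s - geom$ringPx) * (1 - depth) * sin(ang)
    avoid <- morphDilateSlices(ventricle, max(1L, round(4 * geom$sc)))
  } else if (identical(lesion$placement, "periventricular")) {
    side <- if (!is.null(lesion$side)) lesion$side else sample(c(-1, 1), 1)
    uP <- if (!is.null(lesion$uFrac)) lesion$uFrac else runif(1, 0.45, 0.65)
    y0 <- geom$cy + geom$ventY[1] * geom$ay
    y1 <- geom$cy + geom$ventY[2] * geom$ay
    cxL <- geom$cx + side * (geom$lobeOffsPx + geom$lobeHalfPx + 0.85 * rPx)
    cyL <- y0 + uP * (y1 - y0)
    zc0 <- round(geom$zc)
    avoid <- ventricle
  } else stop("unknown lesion placement: ", lesion$placement)

  zz <- seq_len(geom$nz)
  ball <- array(FALSE, c(geom$nx, geom$ny, geom$nz))
  X <- matrix(seq_len(geom$nx), geom$nx, geom$ny)
  Y <- matrix(rep(seq_len(geom$ny), each = geom$nx), geom$nx, geom$ny)
  for (z in zz) {
    dz2 <- ((z - zc0) * spec@sliceMm)^2
    if (dz2 > rMm^2) next
    rSl <- sqrt(rMm^2 - dz2) / spec@pixelMm
    ball[, , z] <- ((X - cxL)^2 + (Y - cyL)^2) <= rSl^2
  }
  lesionMask <- ball & brain & !avoid
  if (!any(lesionMask))
    stop("lesion placement impossible: radius/position leaves no voxel inside the brain")
  lesionMask
}

#' Generate a synthetic head-CT phantom
#'
#' Builds a 3D head CT volume in HU together with ground-truth masks. The
#' ideal head (skull ring, gray/white parenchyma, paired parasagittal
#' lateral ventricles joined by a midline third-ventricle slit, the
#' interhemispheric fissure with optional falx folds, and optional
#' stroke lesions) is constructed on the unrotated grid, then rigidly
#' rotated/translated in-plane, blurred with an in-plane Gaussian PSF and
#' corrupted with additive Gaussian noise. Truth masks undergo the same
#' rigid motion (nearest-neighbour) but are never blurred.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return A list with elements \code{volume} (\linkS4class{CTVolume}) and
#'   \code{truth} (\linkS4class{PhantomTruth}).
#' @examples
#' ph <- generatePhantom(phantomSpec(gridShape = c(128, 128, 9), seed = 42))
#' ph$volume
#' ph$truth@ventricleMask
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  geom <- phantomGeometry(spec)
  nx <- geom$nx; ny <- geom$ny; nz <- geom$nz
  X <- matrix(seq_len(nx), nx, ny)
  Y <- matrix(rep(seq_len(ny), each = nx), nx, ny)

  vol <- array(-1000, c(nx, ny, nz))
  brain <- array(FALSE, c(nx, ny, nz))
  vent <- array(FALSE, c(nx, ny, nz))
  falx <- array(FALSE, c(nx, ny, nz))

  rUnif <- function(n, r) runif(n, r[1], r[2])
  falxSlices <- runif(nz) < spec@falxProbPerSlice

  for (z in seq_len(nz)) {
    m <- phantomSliceMasks(geom, z, X, Y)
    sl <- matrix(-1000, nx, ny)
    nBrain <- sum(m$brain)
    gray <- rUnif(nBrain, spec@grayHuRange)
    sl[m$brain] <- gray
    # feathered white matter: blend white-range values into the gray base
    wIdx <- m$whiteBlend > 0 & m$brain
    wB <- m$whiteBlend[wIdx]
    sl[wIdx] <- wB * rUnif(sum(wIdx), spec@whiteHuRange) + (1 - wB) * sl[wIdx]
    sl[m$ventricle] <- rUnif(sum(m$ventricle), spec@ventricleHuRange)
    sl[m$fissure] <- rUnif(sum(m$fissure), spec@ventricleHuRange)
    sl[m$skull] <- spec@skullHu
    if (falxSlices[z]) {
      # the falx fold: a bright dural line inside the fissure
      f <- phantomFalxMask(geom, z, X, Y) & m$brain & !m$ventricle
      sl[f] <- rUnif(sum(f), spec@grayHuRange) + spec@falxContrastHu
      falx[, , z] <- f
    }
    vol[, , z] <- sl
    brain[, , z] <- m$brain
    vent[, , z] <- m$ventricle
  }

  stroke <- array(FALSE, c(nx, ny, nz))
  for (lesion in spec@strokeSpec) {
    lm <- placeLesion(lesion, geom, spec, brain, vent)
    lm <- lm & !stroke
    vol[lm] <- rUnif(sum(lm), lesion$huRange)
    stroke <- stroke | lm
  }

  # rigid in-plane motion: content rotated by tiltDeg and shifted by shiftPx
  theta <- spec@tiltDeg * pi / 180
  ctr <- c(geom$cx, geom$cy)
  sh <- spec@shiftPx
  if (theta != 0 || any(sh != 0)) {
    moveHU <- function(m) resampleSlice(m, -theta, ctr, pre = sh,
                                        interp = "bilinear", fill = -1000)
    moveMask <- function(m) resampleSlice(m, -theta, ctr, pre = sh,
                                          interp = "nearest", fill = FALSE) > 0.5
    for (z in seq_len(nz)) {
      vol[, , z] <- moveHU(vol[, , z])
      brain[, , z] <- moveMask(brain[, , z])
      vent[, , z] <- moveMask(vent[, , z])
      stroke[, , z] <- moveMask(stroke[, , z])
    }
  }

  if (spec@psfSigmaPx > 0) vol <- blurSlices(vol, spec@psfSigmaPx)
  if (spec@noiseSdHu > 0) vol <- vol + array(rnorm(length(vol), 0, spec@noiseSdHu), dim(vol))

  spacing <- c(spec@pixelMm, spec@pixelMm, spec@sliceMm)
  volume <- ctVolume(vol, spacing)
  truth <- new("PhantomTruth",
               ventricleMask = binaryVolume(vent, spacing = spacing),
               strokeMask = binaryVolume(stroke, spacing = spacing),
               brainMask = binaryVolume(brain, spacing = spacing),
               trueTiltDeg = spec@tiltDeg,
               trueMslOffsetPx = sh[1])
  list(volume = volume, truth = truth)
}

#' Generate a suite of phantoms with varied conditions
#'
#' Draws \code{n} phantoms with per-case seeds derived from
#' \code{masterSeed}. Head tilt is uniform on [-15, 15] degrees and the
#' in-plane shift uniform on [-10, 10] px. The \code{scenarios} vector
#' assigns one of \code{"edge"} (one edge-adjacent stroke lesion, radius
#' U(5, 25) mm, HU band overlapping the ventricular range),
#' \code{"peri"} (one small periventricular lesion touching a ventricle
#' lobe, radius U(4, 8) mm) or \code{"none"} per case; the default mix for
#' n = 30 is 20 edge, 5 peri, 5 none, mirroring the evaluation protocol.
#' Ventricle calibre varies as U(0.7, 1.4) to emulate anatomical
#' ventricle-size differences across patients.
#'
#' @param n number of phantoms (>= 1).
#' @param baseSpec template \code{\link{phantomSpec}} supplying grid, noise
#'   and tissue parameters.
#' @param masterSeed integer; per-case seeds are \code{masterSeed + case}.
#' @param scenarios character vector of length \code{n} (values "edge",
#'   "peri", "none"), or NULL for the default mix.
#' @param varyVentricleSize draw the per-case ventricle calibre from
#'   U(0.7, 1.4) (TRUE, the evaluation-suite default) or keep the base
#'   specification's calibre (FALSE, e.g. for controlled alignment
#'   parameter-recovery experiments).
#' @return A list with \code{cases} (list of \code{generatePhantom}
#'   results) and \code{manifest} (data.frame: case, seed, scenario, tilt,
#'   shift, lesion radius/HU, falx slice count).
#' @export
phantomSuite <- function(n, baseSpec = phantomSpec(), masterSeed = 20170207,
                         scenarios = NULL, varyVentricleSize = TRUE) {
  stopifnot(n >= 1)
  if (is.null(scenarios)) {
    scenarios <- rep("none", n)
    nEdge <- min(n, ceiling(2 * n / 3))
    if (nEdge > 0) scenarios[seq_len(nEdge)] <- "edge"
    nPeri <- min(n - nEdge, ceiling(n / 6))
    if (nPeri > 0) scenarios[nEdge + seq_len(nPeri)] <- "peri"
  }
  stopifnot(length(scenarios) == n)

  cases <- vector("list", n)
  man <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- as.integer(masterSeed + i)
    set.seed(seed_i)
    tilt <- runif(1, -15, 15)
    shift <- runif(2, -10, 10)
    vscale <- if (varyVentricleSize) runif(1, 0.7, 1.4) else
      baseSpec@ventricleWidthScale
    lesions <- list()
    radius <- NA_real_; huLo <- NA_real_; huHi <- NA_real_
    if (scenarios[i] == "edge") {
      radius <- runif(1, 5, 25)
      huLo <- runif(1, 7, 11); huHi <- huLo + runif(1, 5, 8)
      lesions <- list(list(placement = "edge", radiusMm = radius,
                           huRange = c(huLo, huHi)))
    } else if (scenarios[i] == "peri") {
      radius <- runif(1, 4, 8)
      huLo <- runif(1, 9, 12); huHi <- huLo + runif(1, 4, 6)
      lesions <- list(list(placement = "periventricular", radiusMm = radius,
                           huRange = c(huLo, huHi)))
    }
    sp <- phantomSpec(gridShape = baseSpec@gridShape,
                      pixelMm = baseSpec@pixelMm, sliceMm = baseSpec@sliceMm,
                      skullHu = baseSpec@skullHu,
                      ventricleHuRange = baseSpec@ventricleHuRange,
                      whiteHuRange = baseSpec@whiteHuRange,
                      grayHuRange = baseSpec@grayHuRange,
                      falxProbPerSlice = baseSpec@falxProbPerSlice,
                      falxContrastHu = baseSpec@falxContrastHu,
                      tiltDeg = tilt, shiftPx = shift, strokeSpec = lesions,
                      noiseSdHu = baseSpec@noiseSdHu,
                      psfSigmaPx = baseSpec@psfSigmaPx,
                      ventricleWidthScale = vscale, seed = seed_i)
    cases[[i]] <- generatePhantom(sp)
    man[[i]] <- data.frame(case = i, seed = seed_i, scenario = scenarios[i],
                           tiltDeg = tilt, shiftX = shift[1], shiftY = shift[2],
                           ventricleWidthScale = vscale,
                           lesionRadiusMm = radius, lesionHuLo = huLo,
                           lesionHuHi = huHi,
                           strokeVoxels = sum(cases[[i]]$truth@strokeMask@mask))
  }
  list(cases = cases, manifest = do.call(rbind, man))
}

#' Write a phantom and its truth masks to disk
#'
#' Writes the HU volume and each truth mask as NIfTI with correct pixdim.
#'
#' @param ph a \code{generatePhantom} result.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return Invisibly, the written file paths.
#' @export
writePhantom <- function(ph, dir, prefix = "phantom") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    volume = file.path(dir, paste0(prefix, ".nii.gz")),
    ventricle = file.path(dir, paste0(prefix, "_ventricle.nii.gz")),
    stroke = file.path(dir, paste0(prefix, "_stroke.nii.gz")),
    brain = file.path(dir, paste0(prefix, "_brain.nii.gz")))
  writeVolume(ph$volume, paths["volume"])
  writeMask(ph$truth@ventricleMask, ph$volume, paths["ventricle"])
  writeMask(ph$truth@strokeMask, ph$volume, paths["stroke"])
  writeMask(ph$truth@brainMask, ph$volume, paths["brain"])
  invisible(paths)
}
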