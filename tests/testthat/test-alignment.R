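test_that("skull stripping recovers the enclosed brain at the 100 HU rule", {
  ph <- generatePhantom(cleanSmallSpec(seed = 8))
  brain <- stripSkull(ph$volume)
  tr <- maskData(ph$truth@brainMask)
  # interior of the true brain (away from the ring) is fully recovered
  inner <- ventriseg:::morphErodeSlices(tr, 2)
  expect_gt(sum(maskData(brain) & inner) / sum(inner), 0.999)
  # nothing at or above 100 HU (bone) is ever in the brain
  expect_equal(sum(maskData(brain) & voxelData(ph$volume) >= 100), 0)

  expect_error(stripSkull(ctVolume(array(-1000, c(8, 8, 3)))), "no skull")

  # a voxel at exactly 100 HU counts as bone
  v <- boxHeadVolume(inside = 40)
  a <- voxelData(v); a[20, 20, 2] <- 100
  b2 <- stripSkull(ctVolume(a, spacing(v)))
  expect_false(maskData(b2)[20, 20, 2])
})

test_that("the ROI is the half-width band of the smallest brain rectangle", {
  m <- array(FALSE, c(512, 512, 3))
  m[101:400, 151:420, ] <- TRUE
  roi <- defineROI(binaryVolume(m, spacing = c(0.426, 0.426, 5)))
  expect_equal(roi$xRange, c(176, 325))
  expect_equal(roi$yRange, c(1, 512))

  # brain symmetric about the image centre gives a symmetric ROI
  m2 <- array(FALSE, c(100, 100, 3)); m2[21:80, 11:90, ] <- TRUE
  roi2 <- defineROI(binaryVolume(m2, spacing = c(1, 1, 1)))
  expect_equal(roi2$xRange[1] - 1, 100 - roi2$xRange[2])

  # a single nonempty slice supplies the rectangle
  m3 <- array(FALSE, c(100, 100, 3)); m3[31:70, 31:70, 2] <- TRUE
  expect_equal(defineROI(binaryVolume(m3, spacing = c(1, 1, 1)))$slice, 2)
  expect_error(defineROI(binaryVolume(array(FALSE, c(4, 4, 3)),
                                      spacing = c(1, 1, 1))), "empty")
})

test_that("vertical smoothing matches the normalised 7-tap Gaussian", {
  img <- matrix(0, 15, 15)
  img[8, 8] <- 1
  sm <- smoothVertical(img)
  taps <- exp(-((-3:3)^2) / 4)
  taps <- taps / sum(taps)
  expect_equal(sm[8, 5:11], taps)           # spread along y only
  expect_equal(sm[5:11, 8][-4], rep(0, 6))  # nothing along x

  expect_equal(smoothVertical(matrix(3, 9, 9)), matrix(3, 9, 9))

  # a vertical step (varying only in x) is untouched by a y-only filter
  step <- matrix(rep(c(0, 0, 0, 0, 5, 5, 5, 5, 5), 9), 9, 9)
  expect_equal(smoothVertical(step), step)
})

test_that("the horizontal Laplacian mask responds to bright vertical lines", {
  img <- matrix(0, 15, 15)
  img[8, ] <- 7       # 1-px vertical line of height 7
  r <- laplacianResponse(img)
  expect_equal(r[8, 4], 7)
  expect_equal(r[6, 4], -3.5)
  expect_equal(r[10, 4], -3.5)
  expect_equal(laplacianResponse(matrix(4, 9, 9)), matrix(0, 9, 9))

  # left-right mirroring mirrors the response
  img2 <- matrix(rnorm(15 * 15), 15, 15)
  r2 <- laplacianResponse(img2)
  r2m <- laplacianResponse(img2[15:1, ])
  expect_equal(r2m, r2[15:1, ])
})

test_that("edge thresholding selects responses above mean + 2.5 sd", {
  expect_equal(sum(thresholdEdges(matrix(0, 20, 20))), 0)

  r <- matrix(0, 50, 20)          # 1000 px, 1% at +10
  hot <- cbind(seq(3, 48, by = 5), seq(2, 20, by = 2))
  r[hot] <- 10
  t <- mean(r) + 2.5 * sd(r)      # independent recomputation of the rule
  expect_lt(t, 10); expect_gt(t, 0)
  expect_identical(thresholdEdges(r), r > t)
  expect_equal(sum(thresholdEdges(r)), 10)

  # adding a constant leaves the selection unchanged
  expect_identical(thresholdEdges(r + 5), thresholdEdges(r))
})

test_that("3D denoising drops components below thirty voxels", {
  e <- array(FALSE, c(40, 40, 5))
  e[5, 1:29, 2] <- TRUE                 # 29 voxels: removed
  d <- denoiseEdges3D(e)
  expect_equal(sum(maskData(d$mask)), 0)
  expect_equal(nrow(d$points), 0)

  e[5, 1:30, 2] <- TRUE                 # 30 voxels: retained
  d2 <- denoiseEdges3D(e)
  expect_equal(sum(maskData(d2$mask)), 30)
  expect_equal(colnames(d2$points), c("x", "y", "z"))
})

test_that("plane fitting is exact on exact data and matches a TLS oracle", {
  pts <- expand.grid(y = seq(10, 90, by = 10), z = 1:5)
  pts <- cbind(x = 256, pts)[, c("x", "y", "z")]
  p1 <- fitMidsagittalPlane(pts)
  expect_equal(c(p1@a, p1@b, p1@c), c(0, 0, 256))
  expect_equal(p1@residualRMS, 0)

  pts2 <- data.frame(y = runif(40, 1, 100), z = sample(1:7, 40, TRUE))
  pts2 <- cbind(x = 0.05 * pts2$y + 0.3 * pts2$z + 200, pts2)
  p2 <- fitMidsagittalPlane(pts2)
  expect_equal(c(p2@a, p2@b, p2@c), c(0.05, 0.3, 200), tolerance = 1e-10)

  # independent total-least-squares (SVD) fit agrees on exact-plane data
  m <- as.matrix(pts2)
  ctr <- colMeans(m)
  sv <- svd(sweep(m, 2, ctr))
  nrm <- sv$v[, 3]
  aTLS <- -nrm[2] / nrm[1]
  bTLS <- -nrm[3] / nrm[1]
  cTLS <- ctr[1] - aTLS * ctr[2] - bTLS * ctr[3]
  expect_equal(c(p2@a, p2@b, p2@c), unname(c(aTLS, bTLS, cTLS)),
               tolerance = 1e-8)

  expect_null(fitMidsagittalPlane(pts2[1:2, ]))
  # a plane far from vertical is rejected as a fallback signal
  steep <- data.frame(x = seq(1, 100), y = seq(1, 100), z = 1)
  expect_null(fitMidsagittalPlane(steep[, c("x", "y", "z")]))
})

test_that("per-slice MSL follows the fitted plane", {
  mk <- function(a, b, c) new("MidsagittalPlane", a = a, b = b, c = c,
                              residualRMS = 0, nPoints = 10)
  l1 <- mslForSlice(mk(0, 0, 256), 5)
  expect_equal(l1$intercept, 256); expect_equal(l1$theta, 0)
  l2 <- mslForSlice(mk(0, 1, 100), 10)
  expect_equal(l2$intercept, 110)
  l3 <- mslForSlice(mk(0.1, 0, 200), 3)
  expect_equal(l3$theta * 180 / pi, 5.71, tolerance = 1e-2)
})

test_that("alignment undoes the rigid motion and is idempotent", {
  ph <- generatePhantom(phantomSpec(seed = 21, tiltDeg = 10, shiftPx = c(12, 3)))
  brain <- stripSkull(ph$volume)
  lc <- detectLightCurves(ph$volume, brain)
  plane <- fitMidsagittalPlane(lc$points)
  expect_false(is.null(plane))
  al <- alignVolume(ph$volume, plane)

  # brain volume is preserved by the rigid transform within 2%
  brainA <- applyTransformMask(brain, al$transform)
  expect_lt(abs(sum(maskData(brainA)) / sum(maskData(brain)) - 1), 0.02)

  # the aligned truth ventricle is left-right symmetric about the centerline
  ventA <- maskData(applyTransformMask(ph$truth@ventricleMask, al$transform))
  mirror <- ventA[dim(ventA)[1]:1, , ]
  dice <- 2 * sum(ventA & mirror) / (sum(ventA) + sum(mirror))
  expect_gt(dice, 0.9)

  # aligning the aligned volume again is the identity within 0.5 deg / 1 px
  brain2 <- stripSkull(al$volume)
  lc2 <- detectLightCurves(al$volume, brain2)
  plane2 <- fitMidsagittalPlane(lc2$points)
  al2 <- alignVolume(al$volume, plane2)
  expect_lt(abs(al2$transform@theta) * 180 / pi, 0.5)
  expect_lt(max(abs(al2$transform@shiftX)), 1)

  # round trip: resampling the aligned mask back matches the original closely
  back <- resampleMaskToInput(brainA, al$transform)
  expect_gt(2 * sum(maskData(back) & maskData(brain)) /
              (sum(maskData(back)) + sum(maskData(brain))), 0.98)
})

test_that("the fallback plane is the vertical brain-centre plane", {
  m <- array(FALSE, c(64, 64, 3)); m[11:50, 21:44, ] <- TRUE
  p <- fallbackPlane(binaryVolume(m, spacing = c(1, 1, 1)))
  expect_true(p@fallback)
  expect_equal(c(p@a, p@b, p@c), c(0, 0, 30.5))
})
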