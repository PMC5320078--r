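mkVol <- function(a) ctVolume(a, c(1, 1, 1))
allBrain <- function(vol) binaryVolume(array(TRUE, dim(voxelData(vol))), vol)

test_that("threshold segmentation is the band [vMin, t] and monotone in t", {
  a <- array(rep(0:44, length.out = 45), c(5, 3, 3))
  vol <- mkVol(a)
  br <- allBrain(vol)
  f5 <- thresholdSegment(vol, br, 5, 1)
  expect_identical(maskData(f5), a >= 1 & a <= 5)
  # t = vMin keeps only voxels exactly at vMin
  f1 <- thresholdSegment(vol, br, 1, 1)
  expect_identical(maskData(f1), a == 1)
  # monotone inclusion
  f9 <- thresholdSegment(vol, br, 9, 1)
  expect_true(all(!maskData(f5) | maskData(f9)))
  expect_error(thresholdSegment(vol, br, 0, 1), "vMin")
})

test_that("largest 3D component selection is deterministic with raster ties", {
  a <- array(FALSE, c(20, 10, 3))
  a[1:10, 1:5, 1] <- TRUE                  # 50 voxels
  a[13:20, 7:9, 2] <- TRUE                 # 24 voxels
  m <- binaryVolume(a, spacing = c(1, 1, 1))
  lc <- largestComponent3D(m)
  expect_equal(sum(maskData(lc)), 50)
  expect_true(all(maskData(lc)[1:10, 1:5, 1]))
  # single blob: identity
  expect_identical(maskData(largestComponent3D(lc)), maskData(lc))
  # equal-size blobs: the raster-first blob wins, reproducibly
  b <- array(FALSE, c(10, 10, 3))
  b[2:3, 2:3, 1] <- TRUE; b[7:8, 7:8, 3] <- TRUE
  r1 <- largestComponent3D(binaryVolume(b, spacing = c(1, 1, 1)))
  r2 <- largestComponent3D(binaryVolume(b, spacing = c(1, 1, 1)))
  expect_identical(maskData(r1), maskData(r2))
  expect_true(maskData(r1)[2, 2, 1])       # first in raster order
  expect_error(largestComponent3D(binaryVolume(array(FALSE, c(4, 4, 3)),
                                               spacing = c(1, 1, 1))), "empty")
})

test_that("the annulus is the 0.15*Lmin-wide brain-edge band", {
  a <- array(FALSE, c(140, 240, 3))
  a[21:120, 21:220, ] <- TRUE              # 100 x 200 filled rectangle
  ann <- annulusMask(binaryVolume(a, spacing = c(1, 1, 1)))
  expect_equal(ann$lMin, 100)
  expect_equal(ann$widthPx, 15)
  # the band is exactly the outer 15-px frame of the rectangle
  inner <- array(FALSE, dim(a)); inner[36:105, 36:205, ] <- TRUE
  expect_identical(maskData(ann$mask), a & !inner)
  # annulus lies inside the brain and excludes the eroded interior
  expect_equal(sum(maskData(ann$mask) & !a), 0)
  expect_equal(sum(maskData(ann$mask) & inner), 0)
})

test_that("the centred phantom ventricle never touches the annulus", {
  ph <- generatePhantom(cleanSmallSpec(seed = 12))
  brain <- binaryVolume(maskData(ph$truth@brainMask), spacing = spacing(ph$volume))
  ann <- annulusMask(brain)
  expect_equal(sum(maskData(ph$truth@ventricleMask) & maskData(ann$mask)), 0)
})

test_that("edge checking uses a strict 20 px per-slice area rule", {
  ann <- array(FALSE, c(50, 50, 3)); ann[1:10, , ] <- TRUE
  annBV <- binaryVolume(ann, spacing = c(1, 1, 1))
  seg0 <- array(FALSE, c(50, 50, 3)); seg0[30:40, 30:40, 2] <- TRUE
  expect_false(edgeCheck(binaryVolume(seg0, spacing = c(1, 1, 1)), annBV)@detected)

  seg1 <- array(FALSE, c(50, 50, 3)); seg1[3:7, 11:15, 2] <- TRUE  # 25 px inside
  f1 <- edgeCheck(binaryVolume(seg1, spacing = c(1, 1, 1)), annBV)
  expect_true(f1@detected)
  expect_identical(maskData(f1@offendingRegions), seg1)

  seg2 <- array(FALSE, c(50, 50, 3)); seg2[3:7, 11:14, 2] <- TRUE  # exactly 20
  expect_false(edgeCheck(binaryVolume(seg2, spacing = c(1, 1, 1)), annBV)@detected)
})

test_that("stroke extraction and subtraction remove the edge lesion", {
  sp <- phantomSpec(seed = 77, tiltDeg = 4, shiftPx = c(3, -2),
    ventricleWidthScale = 0.8, strokeSpec =
    list(list(placement = "edge", radiusMm = 24, huRange = c(8, 14),
              angleRad = 0.8, depthFrac = 0.05)))
  ph <- generatePhantom(sp)
  res <- suppressWarnings(segmentVentricle(ph$volume))
  expect_true(res@stroke@detected)
  sm <- maskData(ph$truth@strokeMask)
  # the extracted PA covers most of the lesion, the final mask almost none
  expect_equal(sum(maskData(res@final) & sm) / sum(sm), 0, tolerance = 0.05)
  # PA never intersects the subtracted result
  seg <- subtractStroke(res@preliminary, res@stroke)
  expect_equal(sum(maskData(seg) & maskData(res@stroke@paMask)), 0)
  # empty PA is the identity
  none <- new("StrokeFinding", detected = FALSE,
              offendingRegions = ventriseg:::emptyMaskLike(res@preliminary),
              paMask = ventriseg:::emptyMaskLike(res@preliminary))
  expect_identical(maskData(subtractStroke(res@preliminary, none)),
                   maskData(res@preliminary))
})

test_that("critical-threshold bisection matches the exhaustive integer scan", {
  sp <- phantomSpec(seed = 78, strokeSpec =
    list(list(placement = "edge", radiusMm = 20, huRange = c(8, 14),
              angleRad = 4, depthFrac = 0.06)))
  ph <- generatePhantom(sp)
  vol <- ph$volume
  brain <- stripSkull(vol)
  lc <- detectLightCurves(vol, brain)
  al <- alignVolume(vol, fitMidsagittalPlane(lc$points))
  brA <- applyTransformMask(brain, al$transform)
  cl <- clusterBrain(al$volume, brA)
  rg <- estimateVentricleRange(al$volume, cl$candidate)
  ann <- annulusMask(brA)

  tBis <- suppressWarnings(findCriticalThreshold(al$volume, brA, rg, ann$mask))
  # oracle: scan every integer threshold from the public operations
  cleanT <- function(t) {
    f <- thresholdSegment(al$volume, brA, t, vMin(rg))
    if (!any(maskData(f))) return(TRUE)
    !edgeCheck(largestComponent3D(f), ann$mask)@detected
  }
  ts <- ceiling(vMin(rg)):floor(vMax(rg))
  oracle <- if (cleanT(vMax(rg))) vMax(rg) else {
    ok <- ts[vapply(ts, cleanT, logical(1)) & ts < vMax(rg)]
    if (length(ok)) max(ok) else vMin(rg)
  }
  expect_equal(tBis, oracle)
  expect_lte(tBis, vMax(rg))
})

test_that("the adaptive template covers the lateral lobes and excludes lesions", {
  ph <- generatePhantom(cleanSmallSpec(seed = 55))
  vol <- ph$volume
  brain <- stripSkull(vol)
  cl <- clusterBrain(vol, brain)
  rg <- estimateVentricleRange(vol, cl$candidate)
  tpl <- buildTemplate(vol, brain, rg)
  vm <- maskData(ph$truth@ventricleMask)
  expect_gt(sum(maskData(tpl) & vm) / sum(vm), 0.95)
  # built from a single 3D component before dilation: still one component
  lab <- ventriseg:::labelComponents(maskData(tpl), 26)
  expect_equal(attr(lab, "max_label"), 1L)
})

test_that("template application removes disjoint blobs and big out-of-template patches", {
  tpl <- array(FALSE, c(60, 60, 3)); tpl[20:40, 20:40, ] <- TRUE
  tplBV <- binaryVolume(tpl, spacing = c(1, 1, 1))

  seg <- tpl
  segBV <- binaryVolume(seg, spacing = c(1, 1, 1))
  expect_identical(maskData(applyTemplate(segBV, tplBV)), seg)  # seg within template

  seg2 <- seg; seg2[50:55, 50:55, 2] <- TRUE                    # isolated blob
  out2 <- applyTemplate(binaryVolume(seg2, spacing = c(1, 1, 1)), tplBV)
  expect_identical(maskData(out2), seg)

  # a 5x10 appendage (>= 20 px) attached outside the template is removed,
  # a small (< 20 px) protrusion is kept
  seg3 <- seg
  seg3[41:50, 25:29, 2] <- TRUE             # 50 px appendage
  seg3[41:43, 35:36, 2] <- TRUE             # 6 px protrusion
  out3 <- applyTemplate(binaryVolume(seg3, spacing = c(1, 1, 1)), tplBV)
  expect_false(any(maskData(out3)[44:50, 25:29, 2]))
  expect_true(all(maskData(out3)[41:43, 35:36, 2]))

  # an empty template passes everything through
  expect_identical(maskData(applyTemplate(binaryVolume(seg3, spacing = c(1, 1, 1)),
                                          binaryVolume(array(FALSE, dim(seg)),
                                                       spacing = c(1, 1, 1)))),
                   seg3)
})

test_that("refinement closes notches and removes bright calcifications", {
  a <- array(30, c(40, 40, 3))
  seg <- array(FALSE, c(40, 40, 3))
  seg[10:30, 10:30, 2] <- TRUE
  seg[20, 10, 2] <- FALSE                  # 1-px notch on the boundary
  a[15, 15, 2] <- 80                        # calcification inside
  vol <- mkVol(a)
  out <- refineMask(vol, binaryVolume(seg, spacing = c(1, 1, 1)), vMax = 12)
  expect_true(maskData(out)[20, 10, 2])     # notch filled by closing
  expect_false(maskData(out)[15, 15, 2])    # 80 HU > vMax + 30 removed
  # an already-smooth component without bright voxels is unchanged
  a2 <- array(5, c(40, 40, 3))
  seg2 <- array(FALSE, c(40, 40, 3)); seg2[10:30, 10:30, ] <- TRUE
  out2 <- refineMask(mkVol(a2), binaryVolume(seg2, spacing = c(1, 1, 1)), 12)
  expect_identical(maskData(out2), seg2)
  expect_error(refineMask(vol, binaryVolume(array(FALSE, c(40, 40, 3)),
                                            spacing = c(1, 1, 1)), 12), "empty")
})

test_that("the full pipeline is deterministic and accurate end to end", {
  ph <- generatePhantom(phantomSpec(seed = 90, tiltDeg = -7, shiftPx = c(-6, 4)))
  r1 <- segmentVentricle(ph$volume)
  r2 <- segmentVentricle(ph$volume)
  expect_identical(maskData(finalMask(r1)), maskData(finalMask(r2)))
  expect_false(r1@stroke@detected)
  expect_equal(r1@tCritical, vMax(r1@range))   # clean at the top: no branch

  ev <- evaluateSegmentation(finalMask(r1), ph$truth@ventricleMask,
                             ph$truth@brainMask)
  expect_gt(ev$dice, 0.9)

  # the final mask is a single 26-connected component inside the brain
  lab <- ventriseg:::labelComponents(maskData(finalMask(r1)), 26)
  expect_equal(attr(lab, "max_label"), 1L)
  brain <- stripSkull(ph$volume)
  expect_equal(sum(maskData(finalMask(r1)) & !maskData(brain)), 0)
})
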