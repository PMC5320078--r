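bv <- function(a) binaryVolume(a, spacing = c(0.426, 0.426, 5))

test_that("Dice handles identity, disjointness and partial overlap exactly", {
  a <- array(FALSE, c(10, 10, 3)); a[2:3, 2:3, 1] <- TRUE        # 4 voxels
  b <- array(FALSE, c(10, 10, 3)); b[3:4, 2:3, 1] <- TRUE        # 4, overlap 2
  expect_equal(diceCoefficient(bv(a), bv(a)), 1)
  d <- array(FALSE, c(10, 10, 3)); d[8, 8, 3] <- TRUE
  expect_equal(diceCoefficient(bv(a), bv(d)), 0)
  expect_equal(diceCoefficient(bv(a), bv(b)), 0.5)
  expect_warning(e <- diceCoefficient(bv(array(FALSE, c(10, 10, 3))),
                                      bv(array(FALSE, c(10, 10, 3)))), "empty")
  expect_equal(e, 1)
  # tight upper bound 2*min(|Vs|,|Vr|)/(|Vs|+|Vr|)
  set.seed(3)
  for (i in 1:10) {
    x <- array(runif(300) < 0.3, c(10, 10, 3))
    y <- array(runif(300) < 0.4, c(10, 10, 3))
    expect_lte(diceCoefficient(bv(x), bv(y)),
               2 * min(sum(x), sum(y)) / (sum(x) + sum(y)) + 1e-12)
  }
})

test_that("sensitivity and specificity count the confusion matrix in-domain", {
  dom <- array(FALSE, c(20, 25, 2)); dom[, , 1] <- TRUE           # 500 voxels
  ref <- array(FALSE, dim(dom)); ref[1:5, 1:2, 1] <- TRUE         # 10 voxels
  seg <- ref; seg[5, 2, 1] <- FALSE; seg[10, 10, 1] <- TRUE       # 9 TP + 1 FP
  # domain of 1000: use two full slices
  dom2 <- array(TRUE, c(20, 25, 2))
  ss <- sensitivitySpecificity(bv(seg), bv(ref), bv(dom2))
  expect_equal(unname(ss["sensitivity"]), 0.9)
  expect_equal(unname(ss["specificity"]), 989 / 990)

  expect_equal(unname(sensitivitySpecificity(bv(ref), bv(ref), bv(dom2))),
               c(1, 1))
  ss0 <- sensitivitySpecificity(bv(array(FALSE, dim(ref))), bv(ref), bv(dom2))
  expect_equal(unname(ss0), c(0, 1))
  expect_error(sensitivitySpecificity(bv(seg), bv(array(FALSE, dim(ref))),
                                      bv(dom2)), "empty")
  expect_error(sensitivitySpecificity(bv(seg), bv(ref), bv(array(FALSE, dim(ref)))),
               "domain")
})

test_that("boundary RMSE equals the brute-force nearest-point oracle", {
  bruteRMSE <- function(segA, refA, px) {
    d2 <- numeric(0)
    for (z in seq_len(dim(segA)[3])) {
      bs <- ventriseg:::boundarySlices(segA)[, , z]
      br <- ventriseg:::boundarySlices(refA)[, , z]
      ps <- which(bs, arr.ind = TRUE); pr <- which(br, arr.ind = TRUE)
      if (nrow(ps) == 0 || nrow(pr) == 0) next
      for (i in seq_len(nrow(ps)))
        d2 <- c(d2, min((ps[i, 1] - pr[, 1])^2 + (ps[i, 2] - pr[, 2])^2))
    }
    px * sqrt(mean(d2))
  }

  ref <- array(FALSE, c(30, 30, 3)); ref[10:19, 10:19, 2] <- TRUE
  seg <- array(FALSE, c(30, 30, 3)); seg[9:20, 9:20, 2] <- TRUE   # dilated by 1
  got <- boundaryRMSE(bv(seg), bv(ref))
  expect_equal(as.numeric(got), bruteRMSE(seg, ref, 0.426))
  expect_gt(as.numeric(got), 0)
  expect_equal(as.numeric(boundaryRMSE(bv(ref), bv(ref))), 0)

  # random mask pairs against the oracle
  set.seed(11)
  for (i in 1:20) {
    a <- array(FALSE, c(40, 40, 3))
    b <- array(FALSE, c(40, 40, 3))
    a[sample(40, 8), sample(40, 8), sample(3, 1)] <- TRUE
    b[5:30, 5:30, ] <- array(runif(26 * 26 * 3) < 0.2, c(26, 26, 3))
    if (!any(a) || !any(b)) next
    skip <- sum(vapply(1:3, function(z) any(a[, , z]) && !any(b[, , z]),
                       logical(1)))
    got <- suppressWarnings(boundaryRMSE(bv(a), bv(b)))
    expect_equal(as.numeric(got), bruteRMSE(a, b, 0.426),
                 label = sprintf("pair %d", i))
  }

  # direction matters: rmse(seg, ref) uses segmented-to-reference only
  big <- array(FALSE, c(30, 30, 3)); big[5:25, 5:25, 2] <- TRUE
  small <- array(FALSE, c(30, 30, 3)); small[14:16, 14:16, 2] <- TRUE
  expect_false(isTRUE(all.equal(as.numeric(boundaryRMSE(bv(small), bv(big))),
                                as.numeric(boundaryRMSE(bv(big), bv(small))))))
})

test_that("slices with no reference boundary are skipped with a warning", {
  seg <- array(FALSE, c(20, 20, 3)); seg[5:8, 5:8, 1] <- TRUE
  seg[5:8, 5:8, 2] <- TRUE
  ref <- array(FALSE, c(20, 20, 3)); ref[5:8, 5:8, 1] <- TRUE
  expect_warning(r <- boundaryRMSE(bv(seg), bv(ref)), "skipped")
  expect_equal(as.numeric(r), 0)
  expect_equal(attr(r, "skippedSlices"), 1L)
})

test_that("reliability is the strict fraction above d", {
  expect_equal(reliability(c(0.9, 0.8), 0.85), 0.5)
  expect_equal(reliability(c(0.9, 0.8, 0.7), 0), 1)
  dices <- c(0.95, 0.95, 0.9, 0.8)
  expect_equal(reliability(dices, max(dices)), 0)  # strict: nothing exceeds the max
  # brute-force counting over random lists
  set.seed(5)
  for (i in 1:10) {
    v <- runif(17)
    d <- runif(1)
    expect_equal(reliability(v, d), sum(v > d) / length(v))
  }
})

test_that("volume correlation reproduces the product-moment form", {
  expect_equal(volumeCorrelation(c(10, 12, 17, 9), c(10, 12, 17, 9)), 1)
  expect_equal(volumeCorrelation(2 * c(10, 12, 17), c(10, 12, 17)), 1)
  expect_equal(volumeCorrelation(c(1, 2, 3), c(2, 1, 3)), 0.5)
  set.seed(8)
  x <- rnorm(20, 15, 4); y <- x + rnorm(20, 0, 2)
  expect_equal(volumeCorrelation(x, y), cor(x, y))   # stats::cor as oracle
  expect_error(volumeCorrelation(rep(3, 5), 1:5), "variance")
})

test_that("suite summaries report Table-style statistics and a monotone curve", {
  rep1 <- data.frame(id = 1, dice = 0.9, sensitivity = 0.95, specificity = 0.99,
                     rmseMm = 0.2, volSegMl = 15, volRefMl = 14)
  s1 <- summarizeSuite(rep1)
  expect_equal(s1$summary$sd, rep(0, 4))
  expect_false(s1$sdDefined)

  reps <- data.frame(id = 1:4, dice = c(0.9, 1, 0.8, 0.86),
                     sensitivity = runif(4), specificity = runif(4),
                     rmseMm = runif(4), volSegMl = c(10, 15, 20, 12),
                     volRefMl = c(11, 15, 19, 12))
  s <- summarizeSuite(reps)
  expect_equal(s$summary$mean[s$summary$metric == "dice"], 0.89)
  expect_equal(s$summary$sd[1], sd(reps$dice))
  expect_equal(s$reliability$d, seq(0.5, 1, by = 0.01))
  expect_true(all(diff(s$reliability$R) <= 0))
  expect_equal(s$reliability$R[1], 1)
  expect_equal(s$volumeCorrelation, cor(reps$volSegMl, reps$volRefMl))
})
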