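test_that("equidistant resampling preserves endpoints and spacing", {
  ## straight 79 mm fiber: 80 points spaced exactly 1 mm
  f <- resampleEquidistant(rbind(c(0, 0, 0), c(79, 0, 0)))
  expect_identical(nrow(f), 80L)
  expect_equal(diff(f[, 1]), rep(1, 79), tolerance = 1e-12)
  expect_equal(f[1, ], c(0, 0, 0))
  expect_equal(f[80, ], c(79, 0, 0))
  ## idempotence on an already-equidistant fiber
  expect_equal(resampleEquidistant(f), f, tolerance = 1e-9)
  ## quarter-circle arc: equal chords to high relative accuracy
  th <- seq(0, pi / 2, length.out = 4000)
  arc <- cbind(10 * cos(th), 10 * sin(th), 0)
  fa <- resampleEquidistant(arc)
  ch <- sqrt(rowSums(diff(fa)^2))
  expect_lt((max(ch) - min(ch)) / mean(ch), 1e-6)
  ## degenerate input
  expect_error(resampleEquidistant(rbind(c(1, 1, 1), c(1, 1, 1))),
               "zero-length")
})

test_that("bundle PCA captures a smooth bundle and matches the SVD oracle", {
  truth <- curvedTruth(120L)
  streams <- truth@tractogram@streamlines
  m <- fitBundlePCA(streams)
  expect_identical(ncol(m@basis), 80L)
  expect_true(all(diff(m@variances) <= 1e-8 * m@variances[1]))
  expect_gt(sum(m@explained), 0.99)

  ## reconstruction through the truncated basis equals the best rank-k
  ## approximation (SVD oracle)
  D <- t(vapply(streams, function(s)
    as.numeric(t(resampleEquidistant(s))), numeric(240)))
  Dc <- sweep(D, 2, colMeans(D))
  sv <- svd(Dc)
  k <- 80L
  best <- sv$u[, 1:k] %*% diag(sv$d[1:k]) %*% t(sv$v[, 1:k])
  recon <- (Dc %*% m@basis) %*% t(m@basis)
  expect_equal(sqrt(mean((recon - Dc)^2)), sqrt(mean((best - Dc)^2)),
               tolerance = 1e-8)

  ## identical fibers: zero variance, mean = the fiber
  same <- replicate(5, streams[[1]], simplify = FALSE)
  m0 <- suppressWarnings(fitBundlePCA(same))
  expect_lt(max(m0@variances), 1e-12)
  expect_equal(matrix(m0@center, ncol = 3, byrow = TRUE),
               resampleEquidistant(streams[[1]]), tolerance = 1e-9)
  ## too few fibers for 80 components: warned, truncated
  expect_warning(mSmall <- fitBundlePCA(streams[1:10]), "components")
  expect_identical(ncol(mSmall@basis), 9L)
})

test_that("Gaussian fiber sampling is seeded, centered and degenerate-safe", {
  truth <- curvedTruth(120L)
  m <- fitBundlePCA(truth@tractogram@streamlines)
  s1 <- sampleFibers(m, 50, seed = 4)
  s2 <- sampleFibers(m, 50, seed = 4)
  expect_identical(s1, s2)
  expect_false(identical(s1, sampleFibers(m, 50, seed = 5)))

  ## zero-variance model: every sample is the mean fiber
  m0 <- suppressWarnings(
    fitBundlePCA(replicate(3, truth@tractogram@streamlines[[1]],
                           simplify = FALSE)))
  s0 <- sampleFibers(m0, 4, seed = 1)
  for (s in s0)
    expect_equal(s, matrix(m0@center, ncol = 3, byrow = TRUE),
                 tolerance = 1e-9)

  ## sample mean within 3 SE of the model mean per coordinate
  n <- 2000L
  draws <- sampleFibers(m, n, seed = 12)
  M <- t(vapply(draws, function(s) as.numeric(t(s)), numeric(240)))
  se <- sqrt(colSums(m@basis^2 %*% m@variances)) / sqrt(n)
  se <- sqrt(rowSums(sweep(m@basis^2, 2, m@variances, "*"))) / sqrt(n)
  dev <- abs(colMeans(M) - m@center)
  expect_lt(mean(dev > 3 * se + 1e-12), 0.02)   # ~99.7% within 3 SE
})

test_that("mean fiber and fiber distance behave as documented", {
  a <- resampleEquidistant(rbind(c(0, -1, 0), c(79, -1, 0)))
  b <- resampleEquidistant(rbind(c(0, 1, 0), c(79, 1, 0)))
  mf <- meanFiber(list(a, b))
  expect_equal(mf[, 2], rep(0, 80))            # midline
  expect_equal(meanFiber(list(a)), a)          # single fiber: itself

  ## fiber = mean: zero distance; 1 mm perpendicular shift: 80 mm
  expect_equal(fiberDistance(mf, mf), 0)
  sh <- sweep(mf, 2, c(0, 1, 0), "+")
  expect_equal(fiberDistance(sh, mf), 80)

  ## the distance is not symmetric: a short fiber hugging a long fiber's
  ## start is close to it, but the long fiber's far points are not close
  long <- resampleEquidistant(rbind(c(0, 0, 0), c(100, 0, 0)))
  short <- resampleEquidistant(rbind(c(0, 1, 0), c(5, 1, 0)))
  expect_lt(fiberDistance(short, long), fiberDistance(long, short))

  ## segment-projection variant is bounded by the discrete one
  expect_lte(fiberDistance(sh, mf, projectSegments = TRUE),
             fiberDistance(sh, mf))
})

test_that("candidate filtering enforces distance and mask rules", {
  truth <- curvedTruth(120L)
  streams <- truth@tractogram@streamlines
  mf <- meanFiber(streams)
  thr <- populationDistanceThreshold(streams)
  expect_gt(thr, 0)
  ## the mean fiber itself is always accepted
  fl <- filterCandidates(list(mf), mf, thr, truth@wmMask)
  expect_identical(fl$report$accepted, 1L)
  ## one point outside the mask: rejected for the mask reason
  offGrid <- mf; offGrid[40, ] <- c(-50, -50, -50)
  fl2 <- filterCandidates(list(offGrid), mf, 1e9, truth@wmMask)
  expect_identical(fl2$report$rejectedMask, 1L)
  ## far-away candidate: rejected for distance
  far <- sweep(mf, 2, c(0, 0, 1e3), "+")
  fl3 <- filterCandidates(list(far), mf, thr, truth@wmMask)
  expect_identical(fl3$report$rejectedDistance, 1L)

  ## acceptance fraction equals the brute-force count on the candidate set
  m <- fitBundlePCA(streams)
  cand <- sampleFibers(m, 200, seed = 8)
  fl4 <- filterCandidates(cand, mf, thr, truth@wmMask)
  brute <- sum(vapply(cand, function(s) {
    dOk <- fiberDistance(s, mf) <= thr
    vox <- tractoval:::pointVoxel(truth@wmMask@affine, s, truth@gridDim)
    dOk && !anyNA(vox) && all(truth@wmMask@data[vox])
  }, logical(1)))
  expect_identical(fl4$report$accepted, brute)
})

test_that("bundle up-sampling merges tagged fibers that meet every rule", {
  truth <- curvedTruth(120L)
  rois <- truth@roiPairs[[1]]
  b <- selectBundle(truth@tractogram, rois$roi1, rois$roi2, name = "arc")
  expect_gt(length(b@streamlines), 100L)

  ## n = 0: unchanged
  un <- upsampleBundle(b, truth@wmMask, rois$roi1, rois$roi2, n = 0L)
  expect_identical(un$bundle@streamlines, b@streamlines)

  up <- upsampleBundle(b, truth@wmMask, rois$roi1, rois$roi2, n = 300L,
                       seed = 21L)
  merged <- up$bundle
  expect_gt(length(merged@streamlines), length(b@streamlines))
  expect_equal(up$report$nAcceptedTotal + up$report$rejectedDistance +
               up$report$rejectedMask, up$report$nGenerated)
  syn <- which(merged@origin == "synthetic")
  expect_identical(length(syn), up$report$nKept)

  ## every synthetic fiber satisfies distance + mask + both ROIs
  mf <- meanFiber(b@streamlines)
  thr <- populationDistanceThreshold(b@streamlines)
  resel <- selectBundle(
    new("Bundle", streamlines = merged@streamlines[syn],
        affine = b@affine, name = "arc",
        sourceIds = rep(NA_integer_, length(syn)),
        origin = rep("synthetic", length(syn))),
    rois$roi1, rois$roi2)
  expect_identical(length(resel@streamlines), length(syn))
  for (s in merged@streamlines[syn]) {
    expect_lte(fiberDistance(s, mf), thr + 1e-9)
    vox <- tractoval:::pointVoxel(truth@wmMask@affine, s, truth@gridDim)
    expect_true(all(truth@wmMask@data[vox]))
  }
})
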