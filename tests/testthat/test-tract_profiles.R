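## Straight-corridor fixture with ROI slabs at known arc fractions.
profFixture <- function() {
  affine <- diag(c(1, 1, 1, 1))                 # 1 mm voxels for easy math
  dm <- c(100L, 20L, 20L)
  mk <- function(xIdx) {
    m <- array(FALSE, dm)
    m[xIdx, , ] <- TRUE
    new("BinaryMask", data = m, affine = affine)
  }
  list(affine = affine, dm = dm, roi1 = mk(21L), roi2 = mk(81L))
}

test_that("clipping spans the inter-ROI segment with correct tangents", {
  fx <- profFixture()
  ## straight 100 mm fiber along x; ROIs at 20% and 80% of its length
  f <- rbind(c(0, 10, 10), c(99, 10, 10))
  b <- new("Bundle", streamlines = list(f), affine = fx$affine,
           name = "s", sourceIds = 1L, origin = "original")
  cl <- clipToNodes(b, fx$roi1, fx$roi2, nNodes = 100L)
  expect_identical(dim(cl$points), c(1L, 100L, 3L))
  ## nodes span the middle 60% (voxel slabs are 1 mm wide at x = 20, 80)
  expect_equal(cl$points[1, 1, 1], 19.5, tolerance = 0.51)
  expect_equal(cl$points[1, 100, 1], 80.5, tolerance = 0.51)
  ## tangents of a straight fiber all equal its direction
  expect_equal(cl$tangents[1, , 1], rep(1, 100), tolerance = 1e-9)
  expect_equal(cl$tangents[1, , 2], rep(0, 100), tolerance = 1e-9)

  ## an already-clipped fiber re-parameterizes to the same nodes
  clipped <- cl$points[1, , ]
  b2 <- new("Bundle", streamlines = list(clipped), affine = fx$affine,
            name = "s", sourceIds = 1L, origin = "original")
  cl2 <- clipToNodes(b2, fx$roi1, fx$roi2, nNodes = 100L)
  expect_equal(cl2$points[1, , ], clipped, tolerance = 0.6)

  ## a fiber that never reaches roi2 after roi1 is dropped and counted
  noRoi2 <- rbind(c(0, 10, 10), c(50, 10, 10))
  b3 <- new("Bundle", streamlines = list(f, noRoi2), affine = fx$affine,
            name = "s", sourceIds = 1:2, origin = rep("original", 2))
  cl3 <- clipToNodes(b3, fx$roi1, fx$roi2)
  expect_identical(dim(cl3$points)[1], 1L)
  expect_identical(cl3$dropped, 1L)
})

test_that("Mahalanobis weights downweight outliers and respect symmetry", {
  set.seed(5)
  nf <- 30L; nn <- 10L
  pts <- array(rnorm(nf * nn * 3), c(nf, nn, 3))
  W <- mahalanobisWeights(pts)
  expect_equal(colSums(W), rep(1, nn))

  ## coincident fibers: equal weights
  same <- array(rep(1, nf * nn * 3), c(nf, nn, 3))
  expect_equal(mahalanobisWeights(same)[, 1], rep(1 / nf, nf))

  ## a fiber 5 SDs off-core has weight below 1e-4
  off <- pts
  core <- array(rnorm(nf * nn * 3, sd = 1), c(nf, nn, 3))
  core[1, , 1] <- core[1, , 1] + 8     # ~8 SD outlier along x
  Wo <- mahalanobisWeights(core)
  expect_lt(max(Wo[1, ]), 1e-4)

  ## invariance under a rigid transform of all points
  R <- tractoval:::rotationBetween(c(1, 0, 0), c(0, 1, 0))
  moved <- pts
  for (i in seq_len(nf))
    moved[i, , ] <- pts[i, , ] %*% t(R) + matrix(c(5, -3, 2), nn, 3,
                                                 byrow = TRUE)
  expect_equal(mahalanobisWeights(moved), W, tolerance = 1e-9)
})

test_that("scalar profiles sample volumes correctly", {
  fx <- profFixture()
  f1 <- rbind(c(0, 9, 10), c(99, 9, 10))
  f2 <- rbind(c(0, 11, 10), c(99, 11, 10))
  b <- new("Bundle", streamlines = list(f1, f2), affine = fx$affine,
           name = "s", sourceIds = 1:2, origin = rep("original", 2))
  cl <- clipToNodes(b, fx$roi1, fx$roi2, nNodes = 50L)
  W <- mahalanobisWeights(cl$points)

  ## constant volume: profile == the constant
  vol <- array(3.25, fx$dm)
  p <- profileScalar(vol, fx$affine, cl$points, W, "s", "const")
  expect_equal(profileValues(p), rep(3.25, 50))

  ## linear ramp in x: profile equals the ramp at the node x positions
  ramp <- array(rep(seq_len(fx$dm[1]) - 1, prod(fx$dm[2:3])), fx$dm)
  pr <- profileScalar(ramp, fx$affine, cl$points, W, "s", "ramp")
  xNodes <- colSums(W * cl$points[, , 1])
  expect_equal(profileValues(pr), xNodes, tolerance = 1e-6)

  ## NaN voxels are excluded with weight renormalization
  volNA <- vol
  volNA[, 9:10, ] <- NA          # kills fiber 1's samples
  pn <- profileScalar(volNA, fx$affine, cl$points, W, "s", "na")
  expect_equal(profileValues(pn), rep(3.25, 50))
  expect_true(all(pn@nFibers <= 2L))
})

test_that("cone amplitudes partition the sphere and match the global max", {
  ## single-lobe FOD along z (band-limited delta)
  cf <- as.numeric(shBasis(matrix(c(0, 0, 1), 1, 3), 8))
  shf <- new("SHField", coefficients = array(cf, c(1, 1, 1, 45)),
             lmax = 8L, basis = "tractoval-real-even", affine = diag(4))
  cone <- coneSpec()

  ## isotropic FOD: both maxima equal c0 * Y00
  iso <- new("SHField",
             coefficients = array(c(2, rep(0, 44)), c(1, 1, 1, 45)),
             lmax = 8L, basis = "tractoval-real-even", affine = diag(4))
  a <- fodAmplitudes(iso, c(0, 0, 0), c(0, 0, 1), cone)
  expect_equal(as.numeric(a), rep(2 / (2 * sqrt(pi)), 2), tolerance = 1e-9)

  ## tangent along the lobe: longitudinal max dominates
  az <- fodAmplitudes(shf, c(0, 0, 0), c(0, 0, 1), cone)
  expect_gt(az[1], az[2])
  ## tangent perpendicular: the lobe falls outside the cone
  ax <- fodAmplitudes(shf, c(0, 0, 0), c(1, 0, 0), cone)
  expect_equal(as.numeric(ax[2]), as.numeric(az[1]), tolerance = 1e-6)
  expect_lt(ax[1], ax[2])

  ## max(longitudinal, perpendicular) equals the global sphere maximum
  B <- shBasis(cone$directions, 8L)
  expect_equal(max(az), max(as.numeric(B %*% cf)), tolerance = 1e-12)

  ## a direction exactly at the half-angle is perpendicular (strict cone):
  ## with a two-direction sampling sphere at 30 and 31 degrees, the
  ## boundary direction must land in the perpendicular set
  d30 <- c(sin(pi / 6), 0, cos(pi / 6))
  d31 <- c(sin(31 * pi / 180), 0, cos(31 * pi / 180))
  cone2 <- list(halfAngle = pi / 6, directions = rbind(d30, d31))
  a2 <- fodAmplitudes(shf, c(0, 0, 0), c(0, 0, 1), cone2)
  ampBoth <- as.numeric(shBasis(rbind(d30, d31), 8L) %*% cf)
  expect_identical(as.numeric(a2[1]), 0)          # nothing strictly inside
  expect_equal(as.numeric(a2[2]), max(ampBoth))
})

test_that("directional profiles aggregate per-node amplitudes", {
  fx <- profFixture()
  ## zero field: both profiles identically zero
  zeroF <- new("SHField", coefficients = array(0, c(fx$dm, 45)),
               lmax = 8L, basis = "tractoval-real-even", affine = fx$affine)
  f1 <- rbind(c(0, 9, 10), c(99, 9, 10))
  f2 <- rbind(c(0, 11, 10), c(99, 11, 10))
  b <- new("Bundle", streamlines = list(f1, f2), affine = fx$affine,
           name = "s", sourceIds = 1:2, origin = rep("original", 2))
  cl <- clipToNodes(b, fx$roi1, fx$roi2, nNodes = 20L)
  W <- mahalanobisWeights(cl$points)
  cone <- coneSpec(nSphere = 180L)
  pd <- profileDirectional(zeroF, cl$points, cl$tangents, W, cone, "s")
  expect_equal(profileValues(pd$longitudinal), rep(0, 20))
  expect_equal(profileValues(pd$perpendicular), rep(0, 20))

  ## fiber order within the bundle does not matter
  cf <- as.numeric(shBasis(matrix(c(1, 0, 0), 1, 3), 8))
  field <- new("SHField",
               coefficients = array(rep(cf, each = prod(fx$dm)),
                                    c(fx$dm, 45)),
               lmax = 8L, basis = "tractoval-real-even", affine = fx$affine)
  pd1 <- profileDirectional(field, cl$points, cl$tangents, W, cone, "s")
  rev <- c(2L, 1L)
  pd2 <- profileDirectional(field, cl$points[rev, , , drop = FALSE],
                            cl$tangents[rev, , , drop = FALSE],
                            W[rev, , drop = FALSE], cone, "s")
  expect_equal(profileValues(pd1$longitudinal),
               profileValues(pd2$longitudinal), tolerance = 1e-12)
  ## fibers run along x and the lobe is along x: longitudinal dominates
  expect_gt(mean(profileValues(pd1$longitudinal)),
            mean(profileValues(pd1$perpendicular)))
})

test_that("profiles export to a tidy table", {
  p <- new("TractProfile", bundle = "b", metric = "m",
           values = c(1, 2), nFibers = c(3L, 3L), weightSum = c(1, 1))
  df <- profilesToDataFrame(list(p, p))
  expect_identical(nrow(df), 4L)
  expect_identical(names(df), c("bundle", "metric", "node", "value",
                                "nFibers"))
})
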