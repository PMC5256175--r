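test_that("compartment kernels match their closed forms", {
  ## b = 0 and perpendicular stick geometry give no attenuation
  expect_equal(stickAttenuation(0, c(0, 0, 1), c(0, 0, 1)), 1)
  expect_equal(stickAttenuation(3000, c(1, 0, 0), c(0, 0, 1), 1.7e-3), 1)
  ## parallel stick: exp(-b d) = exp(-5.1)
  expect_equal(stickAttenuation(3000, c(0, 0, 1), c(0, 0, 1), 1.7e-3),
               exp(-5.1), tolerance = 1e-12)
  ## zeppelin perpendicular: exp(-b dPerp) = exp(-1.5)
  expect_equal(zeppelinAttenuation(3000, c(1, 0, 0), c(0, 0, 1),
                                   1.7e-3, 0.5e-3), exp(-1.5))
  ## balls
  expect_equal(ballAttenuation(3000, 1.7e-3), exp(-5.1))
  expect_equal(ballAttenuation(3000, 3.0e-3), exp(-9))
  ## oblique angle, general formula
  g <- c(1, 1, 0) / sqrt(2)
  expect_equal(zeppelinAttenuation(3000, g, c(0, 0, 1)),
               exp(-3000 * 0.5e-3))
  ## non-unit inputs rejected
  expect_error(stickAttenuation(3000, c(2, 0, 0), c(0, 0, 1)), "unit")
  expect_error(zeppelinAttenuation(3000, c(1, 0, 0), c(0, 0, 2)), "unit")
})

test_that("segment tracing conserves arc length and yields unit tangents", {
  affine <- diag(c(2.3, 2.3, 2.3, 1))
  dm <- c(10L, 10L, 10L)
  ## straight 10 mm fiber along x
  s <- rbind(c(3, 10, 10), c(13, 10, 10))
  seg <- traceSegments(s, affine, dm)
  expect_equal(sum(seg$length), 10, tolerance = 1e-9)
  expect_true(all(abs(sqrt(seg$tx^2 + seg$ty^2 + seg$tz^2) - 1) < 1e-9))
  ## chord lengths per voxel: voxel boundaries at (i - 0.5) * 2.3 mm
  perVox <- tapply(seg$length, seg$voxel, sum)
  bounds <- sort(c(3, 13, 2.3 * (0:9 + 0.5)))
  bounds <- bounds[bounds >= 3 & bounds <= 13]
  expect_equal(sort(as.numeric(perVox)), sort(diff(bounds)),
               tolerance = 0.02 * 10)
  ## fiber inside one voxel (voxel 4 spans [8.05, 10.35) mm along x)
  s1 <- rbind(c(8.2, 10, 10), c(10.2, 10, 10))
  seg1 <- traceSegments(s1, affine, dm)
  expect_identical(length(unique(seg1$voxel)), 1L)
  expect_equal(sum(seg1$length), 2, tolerance = 1e-9)
  ## zero-length streamline
  seg0 <- traceSegments(rbind(c(1, 1, 1), c(1, 1, 1)), affine, dm)
  expect_identical(nrow(seg0), 0L)
  ## out-of-grid portion dropped and counted
  sOut <- rbind(c(-20, 10, 10), c(10, 10, 10))
  segO <- traceSegments(sOut, affine, dm)
  expect_gt(attr(segO, "droppedLength"), 0)
  expect_equal(sum(segO$length) + attr(segO, "droppedLength"), 30,
               tolerance = 1e-9)
})

test_that("peak extraction finds stick axes on a dense sphere", {
  sc <- testScheme()
  dw <- dwIndices(sc)
  resp <- stickResponse()
  ## single-lobe FOD along z (band-limited delta): one peak within 2 degrees
  cfDelta <- as.numeric(shBasis(matrix(c(0, 0, 1), 1, 3), 8))
  shf <- new("SHField",
             coefficients = array(cfDelta, c(1, 1, 1, 45)),
             lmax = 8L, basis = "tractoval-real-even", affine = diag(4))
  pk <- extractPeaks(shf)
  expect_identical(nrow(pk), 1L)
  expect_angle_lt(c(pk$dx, pk$dy, pk$dz), c(0, 0, 1), 2)

  ## crossing-fiber FOD via CSD of two orthogonal sticks:
  ## two peaks ~90 degrees apart
  sig2 <- 0.5 * stickAttenuation(sc@bvals[dw], sc@bvecs[dw, ], c(1, 0, 0)) +
          0.5 * stickAttenuation(sc@bvals[dw], sc@bvecs[dw, ], c(0, 0, 1))
  shf2 <- csdFit(oneVoxelSignal(sig2), resp, scheme = sc)
  pk2 <- extractPeaks(shf2)
  expect_identical(nrow(pk2), 2L)
  dirs <- as.matrix(pk2[, c("dx", "dy", "dz")])
  ang <- acos(min(1, abs(sum(dirs[1, ] * dirs[2, ])))) * 180 / pi
  expect_gt(ang, 80)

  ## all-zero SH: no peaks
  shf0 <- new("SHField", coefficients = array(0, c(1, 1, 1, 45)),
              lmax = 8L, basis = "tractoval-real-even", affine = diag(4))
  expect_identical(nrow(extractPeaks(shf0)), 0L)
})

test_that("dictionary columns equal direct kernel evaluation", {
  sc <- testScheme()
  dw <- dwIndices(sc)
  params <- compartmentParams()
  affine <- diag(c(2.3, 2.3, 2.3, 1))
  dm <- c(3L, 3L, 3L)
  mask <- new("BinaryMask", data = array(TRUE, dm), affine = affine)
  ## one straight fiber crossing the center voxel along x
  fiber <- rbind(c(2.3 - 1.15 + 0.1, 2.3, 2.3), c(2.3 + 1.15 - 0.1, 2.3, 2.3))
  tg <- tractogram(list(fiber), affine = affine)
  pk <- data.frame(voxel = 14L, dx = 0, dy = 0, dz = 1, id = 1L,
                   amplitude = 1)
  dict <- buildDictionary(tg, pk, sc, params, mask)
  cm <- dict@columnMap
  expect_identical(sum(cm$kind == "intracellular"), 1L)
  expect_identical(sum(cm$kind == "hindered"), 1L)
  expect_equal(sum(cm$kind == "isotropic"), 2 * prod(dm))

  A <- as.matrix(dict@matrix)
  blk <- match(14L, dict@voxels)
  rows <- (blk - 1L) * 65L + seq_len(65L)
  ## intracellular column: segment length x stick profile, b0 row = length
  col <- A[, which(cm$kind == "intracellular")]
  expect_equal(sum(col != 0), 65L)
  len <- 2 * (1.15 - 0.1)
  expect_equal(col[rows[1]], len, tolerance = 1e-9)
  expect_equal(col[rows[-1]],
               len * stickAttenuation(sc@bvals[dw], sc@bvecs[dw, ], c(1, 0, 0)),
               tolerance = 1e-9)
  ## hindered column: zeppelin about z with unit b0 weight
  colH <- A[, which(cm$kind == "hindered")]
  expect_equal(colH[rows[1]], 1)
  expect_equal(colH[rows[-1]],
               zeppelinAttenuation(sc@bvals[dw], sc@bvecs[dw, ], c(0, 0, 1)),
               tolerance = 1e-12)
  ## isotropic columns: ball profiles in every voxel
  iso1 <- A[, which(cm$kind == "isotropic" & cm$voxel == 14 & cm$param == 1)]
  expect_equal(iso1[rows[-1]],
               rep(ballAttenuation(3000, params@dIso[1]), 64),
               tolerance = 1e-12)

  ## two identical fibers give two identical columns (no deduplication)
  tg2 <- tractogram(list(fiber, fiber), affine = affine)
  dict2 <- buildDictionary(tg2, pk, sc, params, mask)
  i2 <- which(dict2@columnMap$kind == "intracellular")
  expect_equal(as.numeric(dict2@matrix[, i2[1]]),
               as.numeric(dict2@matrix[, i2[2]]))

  ## empty tractogram: only hindered + isotropic columns remain
  dict0 <- buildDictionary(tractogram(list()), pk, sc, params, mask)
  expect_identical(sum(dict0@columnMap$kind == "intracellular"), 0L)
  expect_identical(ncol(dict0@matrix), nrow(dict0@columnMap))

  ## removing a streamline removes exactly one column
  expect_identical(ncol(dict2@matrix) - ncol(dict@matrix), 1L)
  ## non-negativity of the operator
  expect_gte(min(dict@matrix), 0)
})

test_that("noiseless phantom signal lies in the ground-truth dictionary span", {
  truth <- crossingTruth()
  dwi <- crossingDWI()
  norm <- normalizeSignal(dwi, truth@wmMask)
  dict <- buildDictionary(truth@tractogram, truth@peaks, testScheme(),
                          compartmentParams(), norm@mask)
  xt <- groundTruthWeights(truth, dict)
  r <- as.numeric(dict@matrix %*% xt) - norm@y
  expect_lt(sqrt(sum(r^2)), 1e-8)
})
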