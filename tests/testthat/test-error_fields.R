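test_that("error signal is the element-wise squared residual", {
  truth <- crossingTruth()
  dwi <- crossingDWI()
  nrm <- normalizeSignal(dwi, truth@wmMask)
  dict <- buildDictionary(truth@tractogram, truth@peaks, testScheme(),
                          compartmentParams(), nrm@mask)
  xt <- groundTruthWeights(truth, dict)
  wTrue <- new("WeightVector", x = xt, objectiveTrace = 0, nIter = 0L,
               converged = TRUE)
  fit <- predictFit(dict, wTrue, dwi, nrm)

  ## perfect fit: zero everywhere
  err <- computeErrorSignal(dwi, fit)
  expect_lt(max(err@data, na.rm = TRUE), 1e-20)
  expect_identical(dim(err@data)[4], 64L)          # b0 dropped

  ## known perturbation delta on one direction of one voxel
  v <- dict@voxels[10]
  ijk <- arrayInd(v, truth@gridDim)
  dwi2 <- dwi
  dwi2@data[ijk[1], ijk[2], ijk[3], 5] <-
    dwi2@data[ijk[1], ijk[2], ijk[3], 5] + 0.25
  err2 <- computeErrorSignal(dwi2, fit)
  expect_equal(err2@data[ijk[1], ijk[2], ijk[3], 4], 0.25^2,
               tolerance = 1e-10)                  # DW index 4 = volume 5
  e <- err2@data[ijk[1], ijk[2], ijk[3], ]
  expect_lt(max(e[-4]), 1e-20)

  ## absolute-residual switch
  errAbs <- computeErrorSignal(dwi2, fit, residual = "absolute")
  expect_equal(errAbs@data[ijk[1], ijk[2], ijk[3], 4], 0.25,
               tolerance = 1e-10)
})

test_that("s = (1,0), sHat = (0,1) gives squared error (1,1)", {
  sc <- acquisitionScheme(c(0, 3000, 3000),
                          rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  data <- array(0, c(1, 1, 1, 3)); data[1, 1, 1, ] <- c(1, 1, 0)
  dwi <- new("DWIVolume", data = data, affine = diag(4), scheme = sc)
  fit <- new("FitResult", sHat = c(1, 0, 1),
             nrmse = array(0, c(1, 1, 1)),
             weights = new("WeightVector", x = numeric(0),
                           objectiveTrace = 0, nIter = 0L, converged = TRUE),
             voxels = 1L)
  err <- computeErrorSignal(dwi, fit)
  expect_equal(as.numeric(err@data[1, 1, 1, ]), c(1, 1))
})

test_that("tensor fit recovers isotropy, stick anisotropy and closed forms", {
  sc <- testScheme()
  dw <- dwIndices(sc)
  G <- sc@bvecs[dw, ]; bdw <- sc@bvals[dw]
  ## isotropic: FA ~ 0
  tIso <- fitTensorFA(oneVoxelSignal(exp(-bdw * 1.7e-3)), sc)
  expect_lt(tIso@fa[1], 0.01)
  ## single stick: FA > 0.9 and correct principal axis
  ax <- c(1, 2, 0.5); ax <- ax / sqrt(sum(ax^2))
  tStick <- fitTensorFA(oneVoxelSignal(stickAttenuation(bdw, G, ax)), sc)
  expect_gt(tStick@fa[1], 0.9)
  expect_angle_lt(tStick@e1[1, 1, 1, ], ax, 2)
  ## closed-form FA of eigenvalues (1, 0, 0)
  expect_equal(faFromEigenvalues(c(1, 0, 0)), 1)
  expect_equal(faFromEigenvalues(c(1, 1, 1)), 0)
  expect_equal(faFromEigenvalues(c(-1, 0, 0)), 0)  # clipped to zero tensor
  ## all-zero voxel excluded as NA
  t0 <- fitTensorFA(oneVoxelSignal(rep(0, 64)), sc)
  expect_true(is.na(t0@fa[1]))
  ## FA invariant to global scaling of the input
  s <- stickAttenuation(bdw, G, ax) + 0.05
  expect_equal(fitTensorFA(oneVoxelSignal(s * 123), sc)@fa[1],
               fitTensorFA(oneVoxelSignal(s), sc)@fa[1], tolerance = 1e-12)
})

test_that("response estimation recovers the stick profile from a phantom", {
  ## phantom of identical single-stick voxels (plus mask ring)
  sc <- testScheme()
  dw <- dwIndices(sc)
  ax <- c(0.6, 0.8, 0)
  dm <- c(6L, 6L, 6L)
  data <- array(0, c(dm, 65))
  sig <- c(1, 0.8 * stickAttenuation(sc@bvals[dw], sc@bvecs[dw, ], ax) +
              0.2 * ballAttenuation(3000, 3.0e-3))
  for (v in seq_len(prod(dm)))
    data[arrayInd(v, dm)[1], arrayInd(v, dm)[2], arrayInd(v, dm)[3], ] <- sig
  dwi <- new("DWIVolume", data = data, affine = diag(c(2.3, 2.3, 2.3, 1)),
             scheme = sc)
  mask <- new("BinaryMask", data = array(TRUE, dm),
              affine = dwi@affine)
  resp <- estimateResponse(dwi, mask, nVoxels = 20L)
  ## closed-form zonal coefficients of the same profile about z
  rlTrue <- shFitZonal(sc@bvecs[dw, ],
                       0.8 * stickAttenuation(sc@bvals[dw], sc@bvecs[dw, ],
                                              c(0, 0, 1)) +
                       0.2 * ballAttenuation(3000, 3.0e-3), 8)
  expect_equal(resp@rl, rlTrue, tolerance = 0.01 * max(abs(rlTrue)))

  ## isotropic-only data: threshold relaxation path triggers a warning
  dataIso <- array(rep(c(1, rep(exp(-9), 64)), each = prod(dm)), c(dm, 65))
  dwiIso <- new("DWIVolume", data = dataIso, affine = dwi@affine, scheme = sc)
  ws <- capture_warnings(estimateResponse(dwiIso, mask))
  expect_true(any(grepl("relaxing", ws)))
})

test_that("CSD sharpens the response into a delta and honors constraints", {
  sc <- testScheme()
  dw <- dwIndices(sc)
  resp <- stickResponse()
  ## response of response: delta-like FOD along z
  sig <- stickAttenuation(sc@bvals[dw], sc@bvecs[dw, ], c(0, 0, 1))
  fod <- csdFit(oneVoxelSignal(sig), resp, scheme = sc)
  dense <- symmetricSphere(20000)
  amp <- as.numeric(shBasis(dense, 8) %*% fod@coefficients[1, 1, 1, ])
  expect_angle_lt(dense[which.max(amp), ], c(0, 0, 1), 2)
  ## default constraint weight keeps negative lobes moderate
  expect_gt(min(amp), -0.05 * max(amp))
  ## strict constraint regime pushes the floor below 1% of the peak
  ## (at the cost of forward fidelity; the two trade off at fixed lmax)
  fodS <- csdFit(oneVoxelSignal(sig), resp, scheme = sc, lambda = 5)
  ampS <- as.numeric(shBasis(dense, 8) %*% fodS@coefficients[1, 1, 1, ])
  expect_gt(min(ampS), -0.01 * max(ampS))
  expect_angle_lt(dense[which.max(ampS), ], c(0, 0, 1), 2)

  ## oblique axis
  ax <- c(1, 1, 1) / sqrt(3)
  fodA <- csdFit(oneVoxelSignal(
    stickAttenuation(sc@bvals[dw], sc@bvecs[dw, ], ax)), resp, scheme = sc)
  ampA <- as.numeric(shBasis(dense, 8) %*% fodA@coefficients[1, 1, 1, ])
  expect_angle_lt(dense[which.max(ampA), ], ax, 2)

  ## zero input: zero coefficients
  fod0 <- csdFit(oneVoxelSignal(rep(0, 64)), resp, scheme = sc)
  expect_identical(max(abs(fod0@coefficients)), 0)

  ## fidelity regime: forward projection of the FOD reproduces the input
  ## signal to < 5% relative L2
  sigA <- stickAttenuation(sc@bvals[dw], sc@bvecs[dw, ], ax)
  fodF <- csdFit(oneVoxelSignal(sigA), resp, scheme = sc, lambda = 0.2)
  fconv <- tractoval:::shConvolutionFactors(resp@rl, 8)
  B <- shBasis(sc@bvecs[dw, ], 8)
  pred <- as.numeric(B %*% (fconv * fodF@coefficients[1, 1, 1, ]))
  expect_lt(sqrt(sum((pred - sigA)^2) / sum(sigA^2)), 0.05)
})

test_that("error FOD of a perfectly fitted phantom is negligible", {
  truth <- crossingTruth()
  dwi <- crossingDWI()
  nrm <- normalizeSignal(dwi, truth@wmMask)
  dict <- buildDictionary(truth@tractogram, truth@peaks, testScheme(),
                          compartmentParams(), nrm@mask)
  wTrue <- new("WeightVector", x = groundTruthWeights(truth, dict),
               objectiveTrace = 0, nIter = 0L, converged = TRUE)
  fit <- predictFit(dict, wTrue, dwi, nrm)
  err <- computeErrorSignal(dwi, fit)
  resp <- stickResponse()
  ## restrict to a core slab to keep the unit test fast
  core <- array(FALSE, truth@gridDim)
  core[6:10, 6:10, 8] <- TRUE
  coreMask <- new("BinaryMask", data = core & truth@wmMask@data,
                  affine = truth@affine)
  errFOD <- csdFit(err, resp, mask = coreMask)
  sigFOD <- csdFit(normalizedDWArray(dwi, nrm), resp, scheme = dwi@scheme,
                   affine = dwi@affine, mask = coreMask)
  vox <- which(coreMask@data)
  B <- shBasis(symmetricSphere(300), 8)
  maxAmp <- function(fld, v) {
    ij <- arrayInd(v, truth@gridDim)
    max(abs(B %*% fld@coefficients[ij[1], ij[2], ij[3], ]))
  }
  mErr <- max(vapply(vox, function(v) maxAmp(errFOD, v), numeric(1)))
  mSig <- max(vapply(vox, function(v) maxAmp(sigFOD, v), numeric(1)))
  expect_lt(mErr, 1e-3 * mSig)
})
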