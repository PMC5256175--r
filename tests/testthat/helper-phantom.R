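## Shared fixtures, built once per test run and memoized.  All fixtures are
## generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

## 16^3 grid, two orthogonal crossing bundles, 60 fibers each.
crossingSpec <- function(nFibers = 60L, seed = 42L) {
  phantomSpec(gridShape = c(16L, 16L, 16L), voxelSize = 2.3,
    bundles = list(
      bundleSpec(rbind(c(2, 17, 17), c(17, 17, 17), c(32, 17, 17)),
                 radius = 3, nFibers = nFibers, icvf = 0.6, name = "bx"),
      bundleSpec(rbind(c(17, 2, 17), c(17, 17, 17), c(17, 32, 17)),
                 radius = 3, nFibers = nFibers, icvf = 0.6, name = "by")),
    seed = seed)
}

crossingTruth <- function() memo("crossingTruth", makeBundles(crossingSpec()))

testScheme <- function() memo("testScheme", phantomScheme())

crossingDWI <- function() memo("crossingDWI",
                               simulateDWI(crossingTruth(), testScheme()))

## single curved bundle used for PCA / up-sampling fixtures
curvedTruth <- function(nFibers = 200L) {
  memo(paste0("curvedTruth", nFibers), {
    spec <- phantomSpec(gridShape = c(30L, 30L, 30L), voxelSize = 2.3,
      bundles = list(bundleSpec(
        rbind(c(5, 10, 34), c(20, 25, 34), c(40, 44, 34), c(60, 55, 34)),
        radius = 3, nFibers = nFibers, icvf = 0.6, name = "arc")),
      seed = 11L)
    makeBundles(spec)
  })
}

## z-aligned stick response for the test scheme
stickResponse <- function() memo("stickResponse", {
  sc <- testScheme()
  dw <- dwIndices(sc)
  rl <- shFitZonal(sc@bvecs[dw, ],
                   stickAttenuation(sc@bvals[dw], sc@bvecs[dw, ], c(0, 0, 1)),
                   lmax = 8L)
  new("ResponseFunction", rl = rl, lmax = 8L)
})

## single-voxel 4D array over the scheme's DW directions
oneVoxelSignal <- function(values) {
  array(values, dim = c(1, 1, 1, length(values)))
}

expect_angle_lt <- function(u, v, degrees) {
  ca <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  expect_lt(acos(min(1, ca)) * 180 / pi, degrees)
}
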