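## End-to-end orchestration in the mandated stage order: segmentation and
## up-sampling strictly before optimization (optimizing before up-sampling
## would assign weights to partial fiber populations), then residual error
## fields, along-tract profiles and optional group statistics.

#' Default pipeline configuration
#'
#' Returns the configuration skeleton consumed by
#' \code{\link{runPipeline}}. Every default matches the standard
#' parameterization: 80 descriptor points, 80 PCA dimensions, 10,000
#' generated fibers per bundle, lmax 8, pi/6 cone, 500 FISTA iterations at
#' relative tolerance 1e-4, 5000 permutations at alpha 0.05.
#'
#' @param dwi,bval,bvec,tractogram,wmMask input paths.
#' @param rois list of per-bundle lists: list(name, roi1, roi2) paths.
#' @param outDir output directory.
#' @param seed global seed, fanned out deterministically per stage.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(dwi, bval, bvec, tractogram, wmMask, rois,
                           outDir, seed = 1L) {
  list(inputs = list(dwi = dwi, bval = bval, bvec = bvec,
                     tractogram = tractogram, wmMask = wmMask, rois = rois),
       outDir = outDir, seed = as.integer(seed),
       stages = list(upsample = TRUE, stats = FALSE),
       upsampling = list(nFibers = 10000L, capFactor = 10, nPoints = 80L,
                         nComponents = 80L),
       optimizer = list(maxIter = 500L, relTol = 1e-4),
       model = list(dParStick = 1.7e-3, dParZeppelin = 1.7e-3,
                    dPerpZeppelin = 0.5e-3, dIso = c(1.7e-3, 3.0e-3)),
       peaks = list(relThreshold = 0.1, minSeparation = 25),
       csd = list(lmax = 8L, nIter = 50L, tau = 0.1, lambda = 1),
       profiles = list(nNodes = 100L, coneHalfAngle = pi / 6,
                       nSphere = 724L),
       stats = list(nPermutations = 5000L, alpha = 0.05, paired = TRUE))
}

#' Run the full evaluation pipeline
#'
#' Stage order is enforced: segment, up-sample (optional), optimize, error
#' fields, profiles, statistics (optional). A manifest (inputs, seeds,
#' per-stage outputs and timings) is written to the output directory
#' together with the configuration, so a run is fully determined by the
#' manifest plus the input files.
#'
#' @param config list as from \code{\link{pipelineConfig}}, or the path of
#'   a YAML file with the same structure.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  for (p in c(cfg$inputs[c("dwi", "bval", "bvec", "tractogram", "wmMask")],
              unlist(lapply(cfg$inputs$rois, function(r) r[c("roi1", "roi2")]))))
    if (!file.exists(p)) stop("input file missing: ", p)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(cfg$outDir, "config.yaml"))
  manifest <- list(inputs = cfg$inputs, seed = cfg$seed, stages = list())
  clock <- function(expr, stage) {
    t0 <- Sys.time()
    val <- force(expr)
    manifest$stages[[stage]]$seconds <<- round(
      as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    val
  }
  message("reading inputs")
  dwi <- readDWI(cfg$inputs$dwi, cfg$inputs$bval, cfg$inputs$bvec)
  wm <- readMask(cfg$inputs$wmMask, dwi)
  tg <- readTractogram(cfg$inputs$tractogram)
  params <- compartmentParams(cfg$model$dParStick, cfg$model$dParZeppelin,
                              cfg$model$dPerpZeppelin, cfg$model$dIso)

  ## stage 1: segmentation
  message("segmenting bundles")
  rois <- lapply(cfg$inputs$rois, function(r)
    list(name = r$name, roi1 = readMask(r$roi1, dwi),
         roi2 = readMask(r$roi2, dwi)))
  bundles <- clock(lapply(rois, function(r)
    selectBundle(tg, r$roi1, r$roi2, name = r$name)), "segment")
  manifest$stages$segment$bundles <- vapply(bundles, length, 1L)

  ## stage 2: up-sampling (before optimization)
  extra <- list()
  if (isTRUE(cfg$stages$upsample)) {
    message("up-sampling bundles")
    ups <- clock(lapply(seq_along(bundles), function(i) {
      upsampleBundle(bundles[[i]], wm, rois[[i]]$roi1, rois[[i]]$roi2,
                     n = cfg$upsampling$nFibers, capFactor = cfg$upsampling$capFactor,
                     nPoints = cfg$upsampling$nPoints,
                     seed = fanSeed(cfg$seed, paste0("upsample", i)))
    }), "upsample")
    manifest$stages$upsample$reports <- lapply(ups, `[[`, "report")
    bundles <- lapply(ups, `[[`, "bundle")
    extra <- unlist(lapply(bundles, function(b)
      b@streamlines[b@origin == "synthetic"]), recursive = FALSE)
    for (i in seq_along(bundles))
      writeTractogram(bundles[[i]],
                      file.path(cfg$outDir, paste0(bundles[[i]]@name, "_up.trk")))
  }
  fullSet <- tractogram(c(tg@streamlines, extra), affine = wm@affine)

  ## stage 3: optimization (strictly after segmentation + up-sampling)
  message("optimizing ", length(fullSet@streamlines), " streamlines")
  norm <- normalizeSignal(dwi, wm)
  resp <- estimateResponse(dwi, norm@mask, lmax = cfg$csd$lmax)
  sigFOD <- csdFit(normalizedDWArray(dwi, norm), resp, scheme = dwi@scheme,
                   affine = dwi@affine, lmax = cfg$csd$lmax,
                   nIter = cfg$csd$nIter, tau = cfg$csd$tau,
                   lambda = cfg$csd$lambda, mask = norm@mask)
  peaks <- extractPeaks(sigFOD, cfg$peaks$relThreshold,
                        cfg$peaks$minSeparation, mask = norm@mask)
  dict <- clock(buildDictionary(fullSet, peaks, dwi@scheme, params,
                                norm@mask), "dictionary")
  weights <- clock(solveNNLS(dict, norm, maxIter = cfg$optimizer$maxIter,
                             relTol = cfg$optimizer$relTol), "optimize")
  fit <- predictFit(dict, weights, dwi, norm)
  manifest$stages$optimize$iterations <- weights@nIter
  manifest$stages$optimize$converged <- weights@converged
  manifest$stages$optimize$finalObjective <-
    weights@objectiveTrace[length(weights@objectiveTrace)]
  manifest$stages$optimize$excludedVoxels <- norm@nExcluded
  manifest$stages$optimize$meanNRMSE <- mean(fit@nrmse, na.rm = TRUE)
  writeVolume(fit@nrmse, file.path(cfg$outDir, "nrmse.nii.gz"),
              affine = dwi@affine)

  ## stage 4: error fields (response re-used from the measured signal)
  message("computing error fields")
  err <- computeErrorSignal(dwi, fit)
  errFOD <- clock(csdFit(err, resp, lmax = cfg$csd$lmax,
                         nIter = cfg$csd$nIter, tau = cfg$csd$tau,
                         lambda = cfg$csd$lambda, mask = norm@mask),
                  "errorFOD")
  errFA <- fitTensorFA(err, mask = norm@mask)
  writeVolume(errFA@fa, file.path(cfg$outDir, "error_fa.nii.gz"),
              affine = dwi@affine)
  writeVolume(errFOD@coefficients,
              file.path(cfg$outDir, "error_fod_sh.nii.gz"),
              affine = dwi@affine)

  ## stage 5: profiles
  message("profiling bundles")
  cone <- coneSpec(cfg$profiles$coneHalfAngle, cfg$profiles$nSphere)
  profs <- clock(unlist(lapply(seq_along(bundles), function(i) {
    b <- bundles[[i]]
    if (!length(b@streamlines)) return(list())
    cl <- clipToNodes(b, rois[[i]]$roi1, rois[[i]]$roi2,
                      cfg$profiles$nNodes)
    if (!dim(cl$points)[1]) return(list())
    w <- mahalanobisWeights(cl$points)
    dir <- profileDirectional(errFOD, cl$points, cl$tangents, w, cone,
                              bundleName = b@name)
    list(profileScalar(fit@nrmse, dwi@affine, cl$points, w, b@name, "nrmse"),
         profileScalar(errFA@fa, dwi@affine, cl$points, w, b@name, "errorFA"),
         dir$longitudinal, dir$perpendicular)
  }), recursive = FALSE), "profiles")
  profDF <- profilesToDataFrame(profs)
  write.csv(profDF, file.path(cfg$outDir, "profiles.csv"), row.names = FALSE)

  ## stage 6: statistics (optional; needs two profile tables)
  if (isTRUE(cfg$stages$stats) && !is.null(cfg$inputs$profilesA)) {
    message("permutation testing")
    a <- as.matrix(read.csv(cfg$inputs$profilesA))
    b <- as.matrix(read.csv(cfg$inputs$profilesB))
    st <- clock(permutationTest(a, b, cfg$stats$nPermutations,
                                cfg$stats$alpha, cfg$stats$paired,
                                seed = fanSeed(cfg$seed, "stats")), "stats")
    write.csv(data.frame(node = seq_along(st$statistic),
                         statistic = st$statistic,
                         pCorrected = st$pCorrected,
                         significant = st$significant),
              file.path(cfg$outDir, "stats.csv"), row.names = FALSE)
  }

  manifest$outputs <- list.files(cfg$outDir)
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a phantom data set to disk in standard formats
#'
#' NIfTI + bvec/bval + TRK + ROI/WM masks, indistinguishable from a real
#' input set.
#'
#' @param truth \linkS4class{PhantomTruth}.
#' @param dwi simulated \linkS4class{DWIVolume}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writePhantom <- function(truth, dwi, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeDWI(dwi, file.path(dir, "dwi.nii.gz"), file.path(dir, "dwi.bval"),
           file.path(dir, "dwi.bvec"))
  writeVolume(truth@wmMask, file.path(dir, "wm_mask.nii.gz"))
  writeTractogram(truth@tractogram, file.path(dir, "truth.trk"))
  for (i in seq_along(truth@roiPairs)) {
    nm <- truth@bundleNames[i]
    writeVolume(truth@roiPairs[[i]]$roi1,
                file.path(dir, paste0(nm, "_roi1.nii.gz")))
    writeVolume(truth@roiPairs[[i]]$roi2,
                file.path(dir, paste0(nm, "_roi2.nii.gz")))
  }
  invisible(dir)
}
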