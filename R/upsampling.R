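## Bundle up-sampling: equidistant 80-point descriptors, PCA truncated to
## 80 of 240 dimensions, bundle-specific Gaussian sampling in the PCA
## space, and rejection of candidates by distance to the population-mean
## fiber and by white-matter mask containment.

#' Resample a streamline to equidistant points
#'
#' Linear interpolation along the polyline at equal arc-length spacing;
#' endpoints are preserved exactly. 80 points (a 240-dimensional
#' descriptor) is the standard descriptor length for bundle PCA.
#'
#' @param streamline N x 3 matrix (world mm), at least 2 distinct points.
#' @param n number of points (default 80).
#' @return n x 3 matrix.
#' @export
#' @examples
#' f <- resampleEquidistant(rbind(c(0, 0, 0), c(79, 0, 0)))
#' diff(f[, 1])[1]    # 1 mm spacing
resampleEquidistant <- function(streamline, n = 80L) {
  resamplePolyline(streamline, n)
}

## Stack fibers into descriptor rows: 80 points x (x, y, z), point-major.
fiberDescriptors <- function(streamlines, n = 80L) {
  t(vapply(streamlines, function(s)
    as.numeric(t(resampleEquidistant(s, n))), numeric(3L * n)))
}

descriptorToFiber <- function(d) matrix(d, ncol = 3, byrow = TRUE)

#' Fit the bundle PCA model
#'
#' Centered PCA of the 240-dimensional descriptors, truncated to the first
#' 80 components (fewer, with a warning, when the fiber count does not
#' support 80). Explained-variance fractions are reported against the full
#' untruncated variance.
#'
#' @param streamlines list of streamlines, or a \linkS4class{Bundle}.
#' @param nPoints descriptor points per fiber (default 80).
#' @param nComponents components retained (default 80).
#' @return A \linkS4class{BundlePCAModel}.
#' @export
fitBundlePCA <- function(streamlines, nPoints = 80L, nComponents = 80L) {
  if (is(streamlines, "Tractogram")) streamlines <- streamlines@streamlines
  nf <- length(streamlines)
  if (nf < 2L) stop("bundle PCA needs at least 2 fibers")
  D <- fiberDescriptors(streamlines, nPoints)
  ctr <- colMeans(D)
  Dc <- sweep(D, 2, ctr)
  sv <- svd(Dc)
  vars <- sv$d^2 / (nf - 1)
  total <- sum(vars)
  k <- min(nComponents, nf - 1L, ncol(D))
  if (k < nComponents)
    warning("only ", k, " components supported by ", nf, " fibers")
  keep <- seq_len(k)
  new("BundlePCAModel", center = ctr,
      basis = sv$v[, keep, drop = FALSE],
      variances = vars[keep],
      explained = if (total > 0) vars[keep] / total else rep(0, k),
      nTrain = as.integer(nf))
}

setMethod("show", "BundlePCAModel", function(object) {
  cat("BundlePCAModel:", length(object@variances), "components from",
      object@nTrain, "fibers;",
      sprintf("%.2f%%", 100 * sum(object@explained)),
      "variance explained\n")
})

#' Sample new fibers from a bundle PCA model
#'
#' Draws from the bundle-specific multivariate Gaussian in the PCA space
#' (diagonal covariance given by the component variances -- components are
#' uncorrelated on the training data), maps back through the basis and
#' mean, and reshapes to 80-point polylines. Deterministic given the seed.
#'
#' @param model \linkS4class{BundlePCAModel}.
#' @param n number of fibers to draw.
#' @param seed integer seed.
#' @return list of n resampled streamlines (nPoints x 3 each).
#' @export
sampleFibers <- function(model, n = 10000L, seed = 1L) {
  if (n == 0L) return(list())
  set.seed(seed)
  k <- length(model@variances)
  Z <- matrix(rnorm(n * k), n, k) *
       rep(sqrt(pmax(0, model@variances)), each = n)
  X <- Z %*% t(model@basis)
  X <- sweep(X, 2, model@center, "+")
  lapply(seq_len(n), function(i) descriptorToFiber(X[i, ]))
}

#' Population-mean fiber
#'
#' Pointwise mean of the equidistantly resampled fibers.
#'
#' @param streamlines list of streamlines or a \linkS4class{Bundle}.
#' @param nPoints descriptor points (default 80).
#' @return nPoints x 3 matrix.
#' @export
meanFiber <- function(streamlines, nPoints = 80L) {
  if (is(streamlines, "Tractogram")) streamlines <- streamlines@streamlines
  descriptorToFiber(colMeans(fiberDescriptors(streamlines, nPoints)))
}

#' Distance of a fiber to the population-mean fiber
#'
#' Sum over the fiber's points of the Euclidean distance to the nearest of
#' the mean fiber's points (discrete point-to-point nearest neighbour; not
#' symmetric in its arguments). With \code{projectSegments = TRUE} the
#' distance to the nearest point on the mean polyline's segments is used
#' instead.
#'
#' @param fiber n x 3 matrix.
#' @param mean m x 3 matrix (the mean fiber).
#' @param projectSegments use segment projection instead of discrete
#'   points (default FALSE).
#' @return distance in mm.
#' @export
fiberDistance <- function(fiber, mean, projectSegments = FALSE) {
  fiber <- matrix(fiber, ncol = 3); mean <- matrix(mean, ncol = 3)
  if (!projectSegments) {
    ## ||f_i - m_j|| via squared-distance matrix
    d2 <- outer(rowSums(fiber^2), rowSums(mean^2), "+") -
          2 * fiber %*% t(mean)
    sum(sqrt(pmax(0, apply(d2, 1, min))))
  } else {
    a <- mean[-nrow(mean), , drop = FALSE]
    b <- mean[-1, , drop = FALSE]
    ab <- b - a
    len2 <- rowSums(ab^2)
    tot <- 0
    for (i in seq_len(nrow(fiber))) {
      ap <- sweep(a, 2, fiber[i, ], "-") * -1
      t <- pmin(1, pmax(0, rowSums(ap * ab) / pmax(len2, 1e-12)))
      proj <- a + ab * t
      tot <- tot + sqrt(min(rowSums(sweep(proj, 2, fiber[i, ])^2)))
    }
    tot
  }
}

#' Distance threshold of a bundle population
#'
#' The maximum distance of any fiber in the population to the population's
#' mean fiber; new fibers farther than this are rejected as outliers.
#'
#' @param streamlines list of streamlines or a \linkS4class{Bundle}.
#' @param nPoints descriptor points.
#' @return threshold in mm.
#' @export
populationDistanceThreshold <- function(streamlines, nPoints = 80L) {
  if (is(streamlines, "Tractogram")) streamlines <- streamlines@streamlines
  mf <- meanFiber(streamlines, nPoints)
  max(vapply(streamlines, function(s)
    fiberDistance(resampleEquidistant(s, nPoints), mf), numeric(1)))
}

#' Filter candidate fibers by distance and mask containment
#'
#' A candidate is accepted when its distance to the mean fiber does not
#' exceed the threshold and all of its points lie inside the white-matter
#' mask.
#'
#' @param candidates list of streamlines.
#' @param meanFiber the population-mean fiber (n x 3).
#' @param distanceThreshold mm.
#' @param wmMask \linkS4class{BinaryMask}.
#' @return list(accepted = streamlines, report = data.frame of counts by
#'   rejection reason: distance, mask, accepted).
#' @export
filterCandidates <- function(candidates, meanFiber, distanceThreshold,
                             wmMask) {
  stopifnot(distanceThreshold >= 0)
  dm <- dim(wmMask@data)
  accepted <- list()
  nDist <- 0L; nMask <- 0L
  for (s in candidates) {
    if (fiberDistance(s, meanFiber) > distanceThreshold) {
      nDist <- nDist + 1L
      next
    }
    vox <- pointVoxel(wmMask@affine, s, dm)
    if (anyNA(vox) || !all(wmMask@data[vox])) {
      nMask <- nMask + 1L
      next
    }
    accepted[[length(accepted) + 1L]] <- s
  }
  list(accepted = accepted,
       report = data.frame(accepted = length(accepted),
                           rejectedDistance = nDist,
                           rejectedMask = nMask))
}

#' Up-sample a bundle
#'
#' End-to-end up-sampling: fit the PCA model on the bundle, draw candidate
#' fibers from the bundle-specific Gaussian, reject by mean-fiber distance
#' and mask containment, re-segment the survivors with the bundle's
#' waypoint ROIs (the same classification criteria applied to the original
#' tractogram), and merge them into the bundle tagged as synthetic.
#' Candidates are drawn in batches of \code{n} until \code{n} fibers are
#' accepted or \code{capFactor * n} candidates have been generated; both
#' counts are reported.
#'
#' @param bundle \linkS4class{Bundle}.
#' @param wmMask \linkS4class{BinaryMask}.
#' @param roi1,roi2 the bundle's waypoint ROIs (for re-segmentation);
#'   NULL skips re-segmentation.
#' @param n target number of accepted new fibers (default 10000).
#' @param seed integer seed.
#' @param capFactor stop after this multiple of n candidates (default 10).
#' @param nPoints descriptor points (default 80).
#' @return list(bundle = merged \linkS4class{Bundle}, report = list with
#'   nGenerated, nAccepted, nKept (after re-segmentation), explained
#'   variance, distance threshold, rejection counts).
#' @export
upsampleBundle <- function(bundle, wmMask, roi1 = NULL, roi2 = NULL,
                           n = 10000L, seed = 1L, capFactor = 10,
                           nPoints = 80L) {
  if (n == 0L)
    return(list(bundle = bundle,
                report = list(nGenerated = 0L, nAccepted = 0L, nKept = 0L)))
  model <- fitBundlePCA(bundle@streamlines, nPoints = nPoints)
  mf <- meanFiber(bundle@streamlines, nPoints)
  thr <- populationDistanceThreshold(bundle@streamlines, nPoints)
  accepted <- list()
  nGen <- 0L
  nAccTotal <- 0L
  batch <- 0L
  rejDist <- 0L; rejMask <- 0L
  while (length(accepted) < n && nGen < capFactor * n) {
    batch <- batch + 1L
    nDraw <- min(n, capFactor * n - nGen)
    cand <- sampleFibers(model, nDraw, seed = fanSeed(seed, paste0("batch", batch)))
    nGen <- nGen + nDraw
    fl <- filterCandidates(cand, mf, thr, wmMask)
    rejDist <- rejDist + fl$report$rejectedDistance
    rejMask <- rejMask + fl$report$rejectedMask
    nAccTotal <- nAccTotal + fl$report$accepted
    room <- n - length(accepted)
    accepted <- c(accepted, fl$accepted[seq_len(min(room, length(fl$accepted)))])
  }
  newTg <- new("Bundle", streamlines = accepted, affine = bundle@affine,
               name = bundle@name,
               sourceIds = rep(NA_integer_, length(accepted)),
               origin = rep("synthetic", length(accepted)))
  if (!is.null(roi1) && !is.null(roi2) && length(accepted))
    newTg <- selectBundle(newTg, roi1, roi2, name = bundle@name)
  merged <- new("Bundle",
                streamlines = c(bundle@streamlines, newTg@streamlines),
                affine = bundle@affine, name = bundle@name,
                sourceIds = c(bundle@sourceIds, newTg@sourceIds),
                origin = c(bundle@origin, newTg@origin))
  list(bundle = merged,
       report = list(nGenerated = nGen, nAcceptedTotal = nAccTotal,
                     nAccepted = length(accepted),
                     nKept = length(newTg@streamlines),
                     acceptanceFraction = nAccTotal / nGen,
                     explainedVariance = sum(model@explained),
                     distanceThreshold = thr,
                     rejectedDistance = rejDist, rejectedMask = rejMask))
}
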