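## Synthetic phantom generator: ground-truth bundle geometries, waypoint
## ROIs, white-matter mask and simulated DWI with a single-shell scheme
## (64 directions on a half-sphere at b = 3000 s/mm^2 plus one b0, 2.3 mm
## isotropic voxels), so every downstream stage is testable without real
## data.

#' PhantomTruth: ground truth of a simulated data set
#'
#' @slot tractogram ground-truth streamlines (world mm).
#' @slot bundleIds integer bundle membership per streamline.
#' @slot bundleNames bundle names.
#' @slot wmMask white-matter \linkS4class{BinaryMask}.
#' @slot roiPairs per-bundle list of (roi1, roi2) \linkS4class{BinaryMask}s,
#'   one-voxel-thick planes perpendicular to the centerline in the first and
#'   last third of the bundle.
#' @slot fractions list of 3D arrays: ic (total intracellular volume
#'   fraction), hindered, iso1, iso2; fractions sum to 1 inside the mask.
#' @slot peaks data.frame of ground-truth fiber directions per voxel
#'   (voxel, dx, dy, dz, bundle, amplitude).
#' @slot fiberWeights per-streamline ground-truth contribution weight.
#' @slot fiberLengths per-streamline in-grid arc length (mm).
#' @slot hinderedRatio hindered-to-intracellular fraction ratio used.
#' @slot isoSplit split of the residual fraction over the two ball
#'   compartments.
#' @slot affine voxel-to-world transform.
#' @slot gridDim grid dimensions.
#' @export
setClass("PhantomTruth",
  representation(tractogram = "Tractogram", bundleIds = "integer",
                 bundleNames = "character", wmMask = "BinaryMask",
                 roiPairs = "list", fractions = "list", peaks = "data.frame",
                 fiberWeights = "numeric", fiberLengths = "numeric",
                 hinderedRatio = "numeric", isoSplit = "numeric",
                 affine = "matrix", gridDim = "integer"))

setMethod("show", "PhantomTruth", function(object) {
  cat("PhantomTruth:", length(object@tractogram@streamlines),
      "streamlines in", length(object@bundleNames), "bundle(s) [",
      paste(object@bundleNames, collapse = ", "), "] on",
      paste(object@gridDim, collapse = " x "), "grid;",
      sum(object@wmMask@data), "WM voxels\n")
})

#' Specify one synthetic bundle
#'
#' @param controlPoints k x 3 matrix of centerline control points (world mm).
#' @param radius tube radius in mm; fibers get Gaussian cross-sectional
#'   offsets with sigma = radius / 2.
#' @param nFibers number of streamlines.
#' @param icvf target intracellular volume fraction at the densest voxel.
#' @param name bundle name.
#' @return list consumed by \code{\link{makeBundles}}.
#' @export
bundleSpec <- function(controlPoints, radius = 3, nFibers = 100,
                       icvf = 0.6, name = "bundle") {
  stopifnot(radius > 0, nFibers >= 1, icvf > 0, icvf <= 0.75)
  list(controlPoints = matrix(as.numeric(controlPoints), ncol = 3),
       radius = radius, nFibers = nFibers, icvf = icvf, name = name)
}

#' Specify a phantom
#'
#' @param gridShape integer grid dimensions (default 20 x 20 x 20).
#' @param voxelSize isotropic voxel size in mm (default 2.3).
#' @param bundles list of \code{\link{bundleSpec}}s.
#' @param snr Rician signal-to-noise ratio on b0 (NULL = noiseless).
#' @param seed integer seed controlling fiber geometry and noise.
#' @export
phantomSpec <- function(gridShape = c(20L, 20L, 20L), voxelSize = 2.3,
                        bundles, snr = NULL, seed = 42L) {
  stopifnot(length(gridShape) == 3L, voxelSize > 0, length(bundles) >= 1L)
  list(gridShape = as.integer(gridShape), voxelSize = voxelSize,
       bundles = bundles, snr = snr, seed = as.integer(seed))
}

## Dense centerline through control points: natural cubic spline per
## coordinate against chord-length parameter.
denseCenterline <- function(controlPoints, n = 200L) {
  u <- cumArcLength(controlPoints)
  u <- u / max(u)
  s <- seq(0, 1, length.out = n)
  cbind(spline(u, controlPoints[, 1], xout = s)$y,
        spline(u, controlPoints[, 2], xout = s)$y,
        spline(u, controlPoints[, 3], xout = s)$y)
}

## Slowly varying normal frame (N1, N2) along a centerline.
centerlineFrame <- function(cl) {
  tang <- unitRows(rbind(cl[2, ] - cl[1, ],
                         cl[-1, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE]))
  meanT <- colMeans(tang)
  ref <- diag(3)[, which.min(abs(meanT)), drop = TRUE]
  n1 <- unitRows(matrix(ref, nrow(cl), 3, byrow = TRUE) -
                 tang * as.numeric(tang %*% ref))
  n2 <- cbind(tang[, 2] * n1[, 3] - tang[, 3] * n1[, 2],
              tang[, 3] * n1[, 1] - tang[, 1] * n1[, 3],
              tang[, 1] * n1[, 2] - tang[, 2] * n1[, 1])
  list(tangent = tang, n1 = n1, n2 = n2)
}

#' Generate ground-truth bundles, masks and ROIs
#'
#' Streamlines are built by sweeping each bundle's centerline (cubic spline
#' through its control points) with Gaussian cross-sectional offsets
#' (sigma = radius/2) plus a smooth low-frequency per-fiber shape jitter.
#' The white-matter mask is the set of traversed voxels dilated by one
#' voxel; waypoint ROIs are one-voxel-thick slabs perpendicular to the
#' centerline at 15 and 85 percent arc length. Ground-truth per-voxel
#' compartment fractions are derived from the streamline geometry itself
#' (fiber segment lengths per voxel), so they are exactly consistent with a
#' signal dictionary built from the same streamlines. Deterministic given
#' the spec seed.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param hinderedRatio hindered fraction as a multiple of the intracellular
#'   fraction in each voxel (default 0.4).
#' @param isoSplit length-2 non-negative weights splitting the residual
#'   fraction over the two isotropic compartments (default c(0.7, 0.3)).
#' @param params \linkS4class{CompartmentParams} (for bookkeeping only here).
#' @return A \linkS4class{PhantomTruth}.
#' @export
makeBundles <- function(spec, hinderedRatio = 0.4, isoSplit = c(0.7, 0.3),
                        params = compartmentParams()) {
  set.seed(spec$seed)
  vs <- spec$voxelSize
  dm <- spec$gridShape
  affine <- diag(c(vs, vs, vs, 1))
  isoSplit <- isoSplit / sum(isoSplit)
  streams <- list()
  bundleIds <- integer()
  roiPairs <- vector("list", length(spec$bundles))
  names(roiPairs) <- vapply(spec$bundles, `[[`, "", "name")
  lo <- -0.5 * vs
  hi <- (dm - 0.5) * vs
  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    cl <- denseCenterline(b$controlPoints)
    fr <- centerlineFrame(cl)
    sigma <- b$radius / 2
    arc <- cumArcLength(cl)
    total <- arc[length(arc)]
    for (fi in seq_len(b$nFibers)) {
      off <- rnorm(2, 0, sigma)
      ## smooth shape jitter: two low-frequency harmonics per normal axis
      amp <- rnorm(4, 0, 0.08 * b$radius)
      ph <- runif(4, 0, 2 * pi)
      u <- arc / total
      j1 <- amp[1] * sin(2 * pi * u + ph[1]) + amp[2] * sin(4 * pi * u + ph[2])
      j2 <- amp[3] * sin(2 * pi * u + ph[3]) + amp[4] * sin(4 * pi * u + ph[4])
      pts <- cl + (off[1] + j1) * fr$n1 + (off[2] + j2) * fr$n2
      ## sample at roughly 1 mm steps
      pts <- resamplePolyline(pts, max(2L, as.integer(ceiling(total))))
      if (any(sweep(pts, 2, lo, "<")) || any(sweep(pts, 2, hi, ">")))
        stop("bundle '", b$name, "' leaves the phantom grid; shrink radius ",
             "or move the centerline")
      streams[[length(streams) + 1L]] <- pts
      bundleIds <- c(bundleIds, bi)
    }
  }
  tg <- tractogram(streams, affine = affine)

  ## per-bundle voxel occupancy and tangent bookkeeping via segment tracing
  nvox <- prod(dm)
  lenByBundle <- vector("list", length(spec$bundles))
  dirByBundle <- vector("list", length(spec$bundles))
  fiberLengths <- numeric(length(streams))
  for (bi in seq_along(spec$bundles)) {
    lenAcc <- numeric(nvox)
    dirAcc <- matrix(0, nvox, 3)
    refDir <- NULL
    for (fi in which(bundleIds == bi)) {
      seg <- traceSegments(streams[[fi]], affine, dm)
      fiberLengths[fi] <- sum(seg$length)
      if (!nrow(seg)) next
      t3 <- as.matrix(seg[, c("tx", "ty", "tz")])
      if (is.null(refDir)) refDir <- t3[1, ]
      sgn <- sign(as.numeric(t3 %*% refDir))    # antipodal sign alignment
      sgn[sgn == 0] <- 1
      t3 <- t3 * sgn
      addL <- tapply(seg$length, seg$voxel, sum)
      vx <- as.integer(names(addL))
      lenAcc[vx] <- lenAcc[vx] + as.numeric(addL)
      for (k in 1:3) {
        add <- tapply(seg$length * t3[, k], seg$voxel, sum)
        dirAcc[vx, k] <- dirAcc[vx, k] + as.numeric(add)
      }
    }
    lenByBundle[[bi]] <- lenAcc
    dirByBundle[[bi]] <- unitRows(dirAcc)
  }
  totalLen <- Reduce(`+`, lenByBundle)

  ## white-matter mask: traversed voxels dilated by one voxel (6-neighborhood)
  occ <- array(totalLen > 0, dim = dm)
  wm <- dilateMask(occ)
  wmMask <- new("BinaryMask", data = wm, affine = affine)

  ## intracellular fractions: shared scale so the densest voxel reaches icvf
  maxDen <- max(totalLen)
  if (maxDen <= 0) stop("no voxel is traversed by any fiber")
  icvfMax <- max(vapply(spec$bundles, `[[`, 0, "icvf"))
  fiberWeights <- numeric(length(streams))
  ic <- numeric(nvox)
  icPerBundle <- vector("list", length(spec$bundles))
  peaks <- list()
  for (bi in seq_along(spec$bundles)) {
    cb <- spec$bundles[[bi]]$icvf / maxDen
    fiberWeights[bundleIds == bi] <- cb
    icb <- cb * lenByBundle[[bi]]
    icPerBundle[[bi]] <- icb
    ic <- ic + icb
    vx <- which(icb > 0)
    peaks[[bi]] <- data.frame(voxel = vx,
                              dx = dirByBundle[[bi]][vx, 1],
                              dy = dirByBundle[[bi]][vx, 2],
                              dz = dirByBundle[[bi]][vx, 3],
                              bundle = bi, id = bi, amplitude = icb[vx])
  }
  peaks <- do.call(rbind, peaks)
  hindered <- hinderedRatio * ic
  if (max(ic + hindered) > 0.98)
    stop("intracellular + hindered fractions exceed 0.98; lower icvf or hinderedRatio")
  iso <- pmax(0, 1 - ic - hindered)
  iso[!wm] <- 1    # mask ring voxels without fibers: purely isotropic
  fractions <- list(ic = array(ic, dm),
                    hindered = array(hindered, dm),
                    iso1 = array(isoSplit[1] * iso, dm),
                    iso2 = array(isoSplit[2] * iso, dm))

  ## waypoint ROIs at 15 / 85 percent of each centerline
  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    cl <- denseCenterline(b$controlPoints)
    fr <- centerlineFrame(cl)
    arc <- cumArcLength(cl); arc <- arc / max(arc)
    occB <- lenByBundle[[bi]] > 0
    mk <- function(frac) {
      i <- which.min(abs(arc - frac))
      roiSlab(cl[i, ], fr$tangent[i, ], occB, affine, dm, vs)
    }
    roiPairs[[bi]] <- list(roi1 = mk(0.15), roi2 = mk(0.85))
  }

  new("PhantomTruth", tractogram = tg, bundleIds = bundleIds,
      bundleNames = vapply(spec$bundles, `[[`, "", "name"),
      wmMask = wmMask, roiPairs = roiPairs, fractions = fractions,
      peaks = peaks, fiberWeights = fiberWeights,
      fiberLengths = fiberLengths, hinderedRatio = hinderedRatio,
      isoSplit = isoSplit, affine = affine, gridDim = dm)
}

## One-voxel-thick slab ROI perpendicular to the centerline, restricted to
## voxels the bundle traverses.
roiSlab <- function(point, normal, occupancy, affine, dm, vs) {
  vx <- which(occupancy)
  ctr <- applyAffine(affine, ijkFromLinear(vx, dm))
  d <- as.numeric(sweep(ctr, 2, point) %*% normal)
  sel <- abs(d) <= 0.75 * vs
  m <- array(FALSE, dm)
  m[vx[sel]] <- TRUE
  new("BinaryMask", data = m, affine = affine)
}

## Binary dilation with the 6-connected structuring element.
dilateMask <- function(m) {
  dm <- dim(m)
  out <- m
  shift <- function(a, ax, by) {
    r <- array(FALSE, dim(a))
    idx <- seq_len(dm[ax])
    src <- idx - by
    ok <- src >= 1 & src <= dm[ax]
    args <- list(r, TRUE, TRUE, TRUE)
    if (ax == 1) r[idx[ok], , ] <- a[src[ok], , ]
    if (ax == 2) r[, idx[ok], ] <- a[, src[ok], ]
    if (ax == 3) r[, , idx[ok]] <- a[, , src[ok]]
    r
  }
  for (ax in 1:3) for (by in c(-1, 1)) out <- out | shift(m, ax, by)
  out
}

#' Single-shell half-sphere acquisition scheme for phantoms
#'
#' 64 electrostatically spread directions on a half-sphere at
#' b = 3000 s/mm^2 plus one leading b = 0 volume.
#'
#' @param nDirections number of diffusion directions.
#' @param bValue shell b-value (s/mm^2).
#' @return An \linkS4class{AcquisitionScheme}.
#' @export
phantomScheme <- function(nDirections = 64L, bValue = 3000) {
  dirs <- sphereDirections(nDirections, hemisphere = TRUE, repulsion = 30L)
  acquisitionScheme(c(0, rep(bValue, nDirections)),
                    rbind(c(0, 0, 0), dirs))
}

#' Simulate the diffusion-weighted signal of a phantom
#'
#' Per voxel the signal is \code{s0} times the fraction-weighted sum of
#' Stick (per ground-truth fiber segment), Zeppelin (per ground-truth
#' direction) and Ball attenuations. The forward computation goes through
#' the same dictionary kernels used for optimization, so a noiseless voxel
#' matching a dictionary column reproduces that column exactly. Rician noise
#' (two independent Gaussian channels, sigma = s0/snr) is applied when snr
#' is set.
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @param scheme an \linkS4class{AcquisitionScheme}
#'   (default \code{phantomScheme()}).
#' @param params \linkS4class{CompartmentParams}.
#' @param s0 non-diffusion-weighted signal amplitude.
#' @param snr Rician SNR on b0; NULL for noiseless.
#' @param seed noise seed.
#' @return A \linkS4class{DWIVolume}; voxels outside the white-matter mask
#'   carry zero signal.
#' @export
simulateDWI <- function(truth, scheme = phantomScheme(),
                        params = compartmentParams(), s0 = 1,
                        snr = NULL, seed = 1L) {
  dict <- buildDictionary(truth@tractogram, truth@peaks, scheme, params,
                          truth@wmMask)
  x <- groundTruthWeights(truth, dict)
  y <- as.numeric(dict@matrix %*% x)
  dm <- truth@gridDim
  nvol <- length(scheme@bvals)
  data <- array(0, c(dm, nvol))
  nxyz <- prod(dm)
  ymat <- matrix(y, nrow = nvol)        # volumes x voxels (row block layout)
  vox <- dict@voxels
  for (vv in seq_len(nvol))
    data[vox + (vv - 1L) * nxyz] <- s0 * ymat[vv, ]
  if (!is.null(snr)) {
    set.seed(seed)
    sigma <- s0 / snr
    n1 <- array(rnorm(length(data), 0, sigma), dim(data))
    n2 <- array(rnorm(length(data), 0, sigma), dim(data))
    data <- sqrt((data + n1)^2 + n2^2)
  }
  new("DWIVolume", data = data, affine = truth@affine, scheme = scheme)
}

#' Ground-truth contribution weights aligned to a dictionary
#'
#' Maps a phantom's per-fiber weights and per-voxel hindered/isotropic
#' fractions onto the column order of a dictionary built from the same
#' streamlines and ground-truth peaks.
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @param dict a \linkS4class{SignalDictionary} built from
#'   \code{truth@tractogram} and \code{truth@peaks}.
#' @return numeric weight vector, one entry per dictionary column.
#' @export
groundTruthWeights <- function(truth, dict) {
  cm <- dict@columnMap
  x <- numeric(nrow(cm))
  fib <- cm$kind == "intracellular"
  x[fib] <- truth@fiberWeights[cm$fiber[fib]]
  hin <- which(cm$kind == "hindered")
  if (length(hin)) {
    key <- paste(truth@peaks$voxel, truth@peaks$bundle)
    amp <- truth@hinderedRatio * truth@peaks$amplitude
    x[hin] <- amp[match(paste(cm$voxel[hin], cm$param[hin]), key)]
  }
  iso <- which(cm$kind == "isotropic")
  if (length(iso)) {
    w1 <- truth@fractions$iso1[cm$voxel[iso]]
    w2 <- truth@fractions$iso2[cm$voxel[iso]]
    firstIso <- cm$param[iso] == 1
    x[iso] <- ifelse(firstIso, w1, w2)
  }
  x
}
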