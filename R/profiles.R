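## Along-tract profiling: each oriented fiber is clipped to its segment
## between the waypoint ROIs and resampled to 100 nodes; node values are
## Mahalanobis-weighted averages across fibers.  Scalar maps are sampled
## trilinearly; directional error-FOD amplitudes are evaluated inside and
## outside a cone around the local fiber tangent.

#' Clip fibers between the waypoint ROIs and parameterize to nodes
#'
#' For each (oriented) fiber the sub-polyline from its first roi1 hit to
#' the first subsequent roi2 hit is resampled to \code{nNodes} equidistant
#' nodes; tangents are normalized central differences. Fibers without a
#' roi2 hit after roi1 are dropped and counted.
#'
#' @param bundle \linkS4class{Bundle} (oriented roi1 -> roi2).
#' @param roi1,roi2 \linkS4class{BinaryMask} waypoint ROIs.
#' @param nNodes nodes per fiber (default 100).
#' @return list(points = array nFibers x nNodes x 3, tangents = same shape,
#'   dropped = count); zero-fiber input yields empty arrays.
#' @export
clipToNodes <- function(bundle, roi1, roi2, nNodes = 100L) {
  pts <- list(); tgs <- list()
  dropped <- 0L
  step <- 0.5
  for (s in bundle@streamlines) {
    L <- cumArcLength(s)
    nf <- max(2L, as.integer(ceiling(L[length(L)] / step)) + 1L)
    fine <- resamplePolyline(s, nf)
    vox <- pointVoxel(roi1@affine, fine, dim(roi1@data))
    ok <- !is.na(vox)
    in1 <- ok & roi1@data[ifelse(ok, vox, 1L)]
    in2 <- ok & roi2@data[ifelse(ok, vox, 1L)]
    h1 <- which(in1)[1]
    if (is.na(h1)) { dropped <- dropped + 1L; next }
    h2 <- which(in2 & seq_along(in2) >= h1)[1]
    if (is.na(h2)) { dropped <- dropped + 1L; next }
    if (h2 - h1 < 1L) { dropped <- dropped + 1L; next }
    seg <- fine[h1:h2, , drop = FALSE]
    nodes <- resamplePolyline(seg, nNodes)
    tang <- rbind(nodes[2, ] - nodes[1, ],
                  nodes[seq(3, nNodes), , drop = FALSE] -
                    nodes[seq(1, nNodes - 2), , drop = FALSE],
                  nodes[nNodes, ] - nodes[nNodes - 1, ])
    pts[[length(pts) + 1L]] <- nodes
    tgs[[length(tgs) + 1L]] <- unitRows(tang)
  }
  nfib <- length(pts)
  P <- array(NA_real_, c(nfib, nNodes, 3))
  Tg <- array(NA_real_, c(nfib, nNodes, 3))
  for (i in seq_len(nfib)) { P[i, , ] <- pts[[i]]; Tg[i, , ] <- tgs[[i]] }
  list(points = P, tangents = Tg, dropped = dropped)
}

#' Mahalanobis fiber weights per node
#'
#' At each node the mean and 3x3 covariance of the fiber points define a
#' Mahalanobis distance D per fiber; weights are proportional to
#' exp(-D^2 / 2) and normalized to sum to one. The covariance is
#' regularized by lambda * I with lambda = 1e-6 * trace / 3 (absolute floor
#' 1e-12) so coincident fibers get equal weights.
#'
#' @param points nFibers x nNodes x 3 array from \code{\link{clipToNodes}}.
#' @return nFibers x nNodes weight matrix (columns sum to 1).
#' @export
mahalanobisWeights <- function(points) {
  nf <- dim(points)[1]; nn <- dim(points)[2]
  W <- matrix(1 / max(nf, 1L), nf, nn)
  if (nf < 2L) return(W)
  for (j in seq_len(nn)) {
    X <- points[, j, ]
    mu <- colMeans(X)
    S <- cov(X)
    lam <- max(1e-6 * sum(diag(S)) / 3, 1e-12)
    S <- S + lam * diag(3)
    Xi <- sweep(X, 2, mu)
    d2 <- rowSums((Xi %*% solve(S)) * Xi)
    w <- exp(-d2 / 2)
    W[, j] <- w / sum(w)
  }
  W
}

#' Profile a scalar volume along a bundle
#'
#' Trilinearly samples the volume at every fiber's node points and forms
#' the Mahalanobis-weighted average per node; NA samples are excluded with
#' weight renormalization.
#'
#' @param volume 3D array (e.g. an NRMSE or FA map).
#' @param affine voxel-to-world affine of the volume.
#' @param points,weights from \code{\link{clipToNodes}} /
#'   \code{\link{mahalanobisWeights}}.
#' @param bundleName,metric names recorded in the profile.
#' @return A \linkS4class{TractProfile}.
#' @export
profileScalar <- function(volume, affine, points, weights,
                          bundleName = "bundle", metric = "scalar") {
  nf <- dim(points)[1]; nn <- dim(points)[2]
  vals <- matrix(NA_real_, nf, nn)
  for (i in seq_len(nf))
    vals[i, ] <- trilinearSample(volume, affine, points[i, , ])
  nodeVals <- numeric(nn); wsum <- numeric(nn); nfb <- integer(nn)
  for (j in seq_len(nn)) {
    ok <- !is.na(vals[, j])
    nfb[j] <- sum(ok)
    if (!any(ok)) { nodeVals[j] <- NA_real_; next }
    w <- weights[ok, j]
    wsum[j] <- sum(w)
    nodeVals[j] <- sum(w * vals[ok, j]) / sum(w)
  }
  new("TractProfile", bundle = bundleName, metric = metric,
      values = nodeVals, nFibers = nfb, weightSum = wsum)
}

#' Cone specification for directional FOD evaluation
#'
#' @param halfAngle half-angle of the cone about the fiber tangent in
#'   radians (default pi/6, i.e. a 30-degree cone). Must lie in (0, pi/2).
#' @param nSphere sampling-sphere size (antipodally symmetrized; ~724
#'   points give sub-degree resolution at order 8).
#' @return list(halfAngle, directions).
#' @export
coneSpec <- function(halfAngle = pi / 6, nSphere = 724L) {
  stopifnot(halfAngle > 0, halfAngle < pi / 2)
  list(halfAngle = halfAngle, directions = symmetricSphere(nSphere))
}

#' Longitudinal and perpendicular FOD amplitudes at a point
#'
#' Evaluates the SH function (coefficients trilinearly interpolated at the
#' point) on the sampling sphere. The longitudinal maximum is taken over
#' directions strictly inside the cone around the tangent (angle computed
#' on |cos|, folding antipodal lobes); the perpendicular maximum over all
#' remaining directions, so directions exactly on the cone boundary count
#' as perpendicular.
#'
#' @param shField \linkS4class{SHField}.
#' @param point world-mm 3-vector.
#' @param tangent unit 3-vector.
#' @param cone a \code{\link{coneSpec}}.
#' @return c(longitudinal, perpendicular) maxima; c(0, 0) for a zero/NA SH.
#' @export
fodAmplitudes <- function(shField, point, tangent, cone = coneSpec()) {
  cf <- trilinearSample(shField@coefficients, shField@affine,
                        matrix(point, 1, 3))
  if (anyNA(cf)) return(c(longitudinal = 0, perpendicular = 0))
  B <- shBasis(cone$directions, shField@lmax)
  amp <- as.numeric(B %*% as.numeric(cf))
  inCone <- abs(as.numeric(cone$directions %*% tangent)) > cos(cone$halfAngle)
  lon <- if (any(inCone)) max(amp[inCone]) else 0
  per <- if (any(!inCone)) max(amp[!inCone]) else 0
  c(longitudinal = lon, perpendicular = per)
}

#' Directional error-FOD profiles along a bundle
#'
#' Per fiber and node the longitudinal and perpendicular FOD amplitude
#' maxima (cone about the local tangent) are evaluated and averaged with
#' the Mahalanobis weights.
#'
#' @param shField \linkS4class{SHField} (e.g. the error FOD).
#' @param points,tangents,weights from \code{\link{clipToNodes}} /
#'   \code{\link{mahalanobisWeights}}.
#' @param cone a \code{\link{coneSpec}}.
#' @param bundleName name recorded in the profiles.
#' @return list(longitudinal, perpendicular), both
#'   \linkS4class{TractProfile}s.
#' @export
profileDirectional <- function(shField, points, tangents, weights,
                               cone = coneSpec(), bundleName = "bundle") {
  nf <- dim(points)[1]; nn <- dim(points)[2]
  B <- shBasis(cone$directions, shField@lmax)
  cosHalf <- cos(cone$halfAngle)
  lonV <- matrix(NA_real_, nf, nn)
  perV <- matrix(NA_real_, nf, nn)
  for (i in seq_len(nf)) {
    cf <- trilinearSample(shField@coefficients, shField@affine,
                          points[i, , ])                     # nn x ncoef
    amp <- B %*% t(cf)                                       # ndir x nn
    ca <- abs(cone$directions %*% t(tangents[i, , ]))        # ndir x nn
    inCone <- ca > cosHalf
    for (j in seq_len(nn)) {
      a <- amp[, j]
      if (anyNA(a)) next
      m <- inCone[, j]
      lonV[i, j] <- if (any(m)) max(a[m]) else 0
      perV[i, j] <- if (any(!m)) max(a[!m]) else 0
    }
  }
  agg <- function(vals, metric) {
    nodeVals <- numeric(nn); wsum <- numeric(nn); nfb <- integer(nn)
    for (j in seq_len(nn)) {
      ok <- !is.na(vals[, j])
      nfb[j] <- sum(ok)
      if (!any(ok)) { nodeVals[j] <- NA_real_; next }
      w <- weights[ok, j]
      wsum[j] <- sum(w)
      nodeVals[j] <- sum(w * vals[ok, j]) / sum(w)
    }
    new("TractProfile", bundle = bundleName, metric = metric,
        values = nodeVals, nFibers = nfb, weightSum = wsum)
  }
  list(longitudinal = agg(lonV, "errorFODlongitudinal"),
       perpendicular = agg(perV, "errorFODperpendicular"))
}

#' Export profiles as a tidy data.frame
#'
#' @param profiles list of \linkS4class{TractProfile}s.
#' @return data.frame(bundle, metric, node, value, nFibers).
#' @export
profilesToDataFrame <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p)
    data.frame(bundle = p@bundle, metric = p@metric,
               node = seq_along(p@values), value = p@values,
               nFibers = p@nFibers)))
}
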