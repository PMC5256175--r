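## Stick-Zeppelin-Ball signal kernels.  Attenuations are dimensionless
## fractions of the b0 signal; b in s/mm^2, diffusivities in mm^2/s, g and v
## unit vectors.

checkUnit <- function(u, what) {
  u <- matrix(u, ncol = 3)
  if (any(abs(sqrt(rowSums(u^2)) - 1) > 1e-6))
    stop(what, " must be unit vector(s)")
  u
}

#' Stick (zero-radius cylinder) signal attenuation
#'
#' \code{exp(-b * dPar * (g . v)^2)}: free diffusion along the fiber axis
#' \code{v}, none across it. Models the intracellular compartment.
#'
#' @param b b-value(s), s/mm^2.
#' @param g gradient direction(s), unit 3-vector or n x 3 matrix.
#' @param v fiber axis, unit 3-vector.
#' @param dPar parallel diffusivity, mm^2/s.
#' @return attenuation in (0, 1], vectorized over rows of \code{g}.
#' @export
#' @examples
#' stickAttenuation(3000, c(1, 0, 0), c(0, 0, 1), 1.7e-3)  # perpendicular: 1
stickAttenuation <- function(b, g, v, dPar = 1.7e-3) {
  g <- checkUnit(g, "g"); v <- as.numeric(checkUnit(v, "v"))
  stopifnot(all(b >= 0), dPar > 0)
  ct <- as.numeric(g %*% v)
  exp(-b * dPar * ct^2)
}

#' Zeppelin (axially symmetric tensor) signal attenuation
#'
#' \code{exp(-b * (dPerp + (dPar - dPerp) * (g . v)^2))}: the hindered
#' extracellular compartment around a fiber population along \code{v}.
#'
#' @inheritParams stickAttenuation
#' @param dPerp perpendicular diffusivity, mm^2/s (must be < dPar).
#' @export
zeppelinAttenuation <- function(b, g, v, dPar = 1.7e-3, dPerp = 0.5e-3) {
  g <- checkUnit(g, "g"); v <- as.numeric(checkUnit(v, "v"))
  stopifnot(all(b >= 0), dPerp > 0, dPerp < dPar)
  ct <- as.numeric(g %*% v)
  exp(-b * (dPerp + (dPar - dPerp) * ct^2))
}

#' Ball (isotropic) signal attenuation
#'
#' \code{exp(-b * d)}: free or hindered isotropic diffusion (CSF, gray
#' matter partial volume).
#'
#' @inheritParams stickAttenuation
#' @param d isotropic diffusivity, mm^2/s.
#' @export
ballAttenuation <- function(b, d) {
  stopifnot(all(b >= 0), d > 0)
  exp(-b * d)
}

#' Trace a streamline through a voxel grid
#'
#' Resamples the streamline to a fine equidistant step and assigns each
#' segment to the voxel containing its midpoint, yielding per-segment
#' (voxel, length, unit tangent) records whose lengths sum to the in-grid
#' arc length. Segments whose midpoint falls outside the grid are dropped
#' and counted.
#'
#' @param streamline N x 3 matrix, world mm.
#' @param affine voxel-to-world 4x4 affine of the grid.
#' @param gridDim integer grid dimensions (x, y, z).
#' @param step resampling step in mm (default 0.5; chord-in-voxel lengths
#'   accurate to < 2 percent at typical voxel sizes).
#' @return data.frame with columns voxel (1-based linear index), length (mm),
#'   tx, ty, tz (unit tangent); attribute \code{droppedLength} holds the
#'   out-of-grid arc length in mm. Zero rows for a zero-length streamline.
#' @export
traceSegments <- function(streamline, affine, gridDim, step = 0.5) {
  streamline <- matrix(as.numeric(streamline), ncol = 3)
  L <- cumArcLength(streamline)
  total <- L[length(L)]
  empty <- data.frame(voxel = integer(), length = numeric(),
                      tx = numeric(), ty = numeric(), tz = numeric())
  attr(empty, "droppedLength") <- 0
  if (total <= 0) return(empty)
  n <- max(2L, as.integer(ceiling(total / step)) + 1L)
  pts <- resamplePolyline(streamline, n)
  seg <- pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  keep <- len > 0
  mid <- (pts[-1, , drop = FALSE] + pts[-n, , drop = FALSE]) / 2
  tang <- unitRows(seg)
  vox <- linearIndex(voxelFloor(worldToVoxel(affine, mid) + 0.5), gridDim)
  inGrid <- !is.na(vox) & keep
  out <- data.frame(voxel = vox[inGrid], length = len[inGrid],
                    tx = tang[inGrid, 1], ty = tang[inGrid, 2],
                    tz = tang[inGrid, 3])
  attr(out, "droppedLength") <- sum(len[!inGrid & keep])
  out
}

## Equidistant resampling of a polyline to n points (linear interpolation
## along arc length, endpoints preserved).  Workhorse shared by tracing and
## the 80-point fiber descriptors.
resamplePolyline <- function(pts, n) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  L <- cumArcLength(pts)
  total <- L[length(L)]
  if (total <= 0) stop("cannot resample a zero-length polyline")
  ## drop duplicate arc-length knots (repeated points)
  keep <- c(TRUE, diff(L) > 0)
  pts <- pts[keep, , drop = FALSE]
  L <- L[keep]
  s <- seq(0, total, length.out = n)
  cbind(approx(L, pts[, 1], xout = s)$y,
        approx(L, pts[, 2], xout = s)$y,
        approx(L, pts[, 3], xout = s)$y)
}
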