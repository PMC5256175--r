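## Shared geometry / array helpers.

#' @importFrom stats approx spline rnorm runif optim cov sd var median
#' @importFrom utils read.table write.table read.csv write.csv tail
NULL

#' Apply a 4x4 affine to a set of 3D points
#'
#' @param affine 4x4 matrix.
#' @param pts n x 3 matrix of points.
#' @return n x 3 matrix of transformed points.
#' @keywords internal
applyAffine <- function(affine, pts) {
  pts <- matrix(pts, ncol = 3)
  sweep(pts %*% t(affine[1:3, 1:3, drop = FALSE]), 2, affine[1:3, 4], "+")
}

## World mm -> continuous 0-based voxel index.
worldToVoxel <- function(affine, pts) {
  applyAffine(solve(affine), pts)
}

## Continuous 0-based voxel index -> integer ijk under the half-open
## convention [i, i+1).  Returns n x 3 integer matrix (0-based).
voxelFloor <- function(vox) {
  matrix(as.integer(floor(vox)), ncol = 3)
}

## 0-based ijk -> 1-based linear index into an array of dim `dm`;
## NA for out-of-grid voxels.
linearIndex <- function(ijk, dm) {
  ok <- ijk[, 1] >= 0 & ijk[, 1] < dm[1] &
        ijk[, 2] >= 0 & ijk[, 2] < dm[2] &
        ijk[, 3] >= 0 & ijk[, 3] < dm[3]
  idx <- 1L + ijk[, 1] + dm[1] * (ijk[, 2] + dm[2] * ijk[, 3])
  idx[!ok] <- NA_integer_
  idx
}

## Inverse of linearIndex: 1-based linear -> 0-based ijk matrix.
ijkFromLinear <- function(lin, dm) {
  lin0 <- lin - 1L
  i <- lin0 %% dm[1]
  j <- (lin0 %/% dm[1]) %% dm[2]
  k <- lin0 %/% (dm[1] * dm[2])
  cbind(i, j, k)
}

#' Trilinear interpolation of a 3D (or 4D) volume at world points
#'
#' For a 4D volume every 4th-dimension channel is interpolated, returning an
#' n x nchan matrix. Sampling positions map voxel centers to integer indices;
#' points outside the grid return NA.
#'
#' @param vol 3D or 4D array.
#' @param affine voxel-to-world 4x4 affine.
#' @param pts n x 3 world-mm points.
#' @return numeric vector (3D input) or n x nchan matrix (4D input).
#' @keywords internal
trilinearSample <- function(vol, affine, pts) {
  dm <- dim(vol)
  is4d <- length(dm) == 4L
  nchan <- if (is4d) dm[4] else 1L
  v <- worldToVoxel(affine, pts)          # voxel centers at integers
  n <- nrow(v)
  f <- floor(v)
  w <- v - f                              # fractional part
  out <- matrix(NA_real_, n, nchan)
  d3 <- dm[1:3]
  nxyz <- prod(d3)
  ## corner offsets
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ijk <- cbind(f[, 1] + dx, f[, 2] + dy, f[, 3] + dz)
    wt <- (if (dx == 1) w[, 1] else 1 - w[, 1]) *
          (if (dy == 1) w[, 2] else 1 - w[, 2]) *
          (if (dz == 1) w[, 3] else 1 - w[, 3])
    lin <- linearIndex(voxelFloor(ijk), d3)
    ok <- !is.na(lin) & wt > 0
    if (!any(ok)) next
    if (is4d) {
      base <- lin[ok]
      vals <- vapply(seq_len(nchan), function(ch)
        vol[base + (ch - 1L) * nxyz], numeric(sum(ok)))
      vals <- matrix(vals, ncol = nchan)
      cur <- out[ok, , drop = FALSE]
      cur[is.na(cur)] <- 0
      out[ok, ] <- cur + wt[ok] * vals
    } else {
      cur <- out[ok]
      cur[is.na(cur)] <- 0
      out[ok] <- cur + wt[ok] * vol[lin[ok]]
    }
  }
  ## any corner out of grid -> NA already propagates only where no corner hit;
  ## enforce full NA when any needed corner was outside
  inside <- v[, 1] >= 0 & v[, 1] <= d3[1] - 1 &
            v[, 2] >= 0 & v[, 2] <= d3[2] - 1 &
            v[, 3] >= 0 & v[, 3] <= d3[3] - 1
  if (is4d) { out[!inside, ] <- NA_real_; out } else { out[!inside] <- NA_real_; as.numeric(out) }
}

## World point -> 1-based linear voxel index (NA outside the grid).  Voxel
## centers sit at integer continuous indices, so a voxel's half-open extent
## is [i - 0.5, i + 0.5); floor(c + 0.5) implements that convention.
pointVoxel <- function(affine, pts, gridDim) {
  linearIndex(voxelFloor(worldToVoxel(affine, pts) + 0.5), gridDim)
}

#' Deterministic fan-out of one global seed into per-stage seeds
#'
#' Hashes a stage label against the global seed so every pipeline stage
#' gets its own reproducible seed below 2^31 from a single knob.
#'
#' @param seed integer global seed.
#' @param stage stage label.
#' @return integer stage seed.
#' @export
fanSeed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435.0 + h * 97.0) %% 2147483629)
}

## Arc lengths of a polyline (n x 3): cumulative, starting at 0.
cumArcLength <- function(pts) {
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(d))
}

## Normalize rows of a matrix to unit length (zero rows left as zero).
unitRows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

## 3x3 rotation taking unit vector `from` onto unit vector `to`.
rotationBetween <- function(from, to) {
  from <- from / sqrt(sum(from^2)); to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c_ <- sum(from * to)
  if (c_ < -1 + 1e-12) {     # opposite: rotate pi about any perpendicular axis
    p <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- p - sum(p * from) * from
    axis <- axis / sqrt(sum(axis^2))
    return(2 * outer(axis, axis) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}
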