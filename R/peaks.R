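## FOD peak extraction: local maxima of the per-voxel SH function on a dense
## half-sphere, refined by local optimization and filtered by relative
## amplitude and minimum angular separation.
##
## Peak tables are plain data.frames with columns voxel (1-based linear
## index), dx, dy, dz (unit direction), id (within-voxel rank) and
## amplitude; the same layout carries ground-truth phantom directions, so
## dictionaries can be built from either source.

#' Extract FOD peaks from an SH field
#'
#' @param shField an \linkS4class{SHField}.
#' @param relThreshold keep peaks with amplitude at least this fraction of
#'   the voxel's maximum amplitude (default 0.1).
#' @param minSeparation minimum angular separation between peaks in degrees
#'   (default 25).
#' @param mask optional \linkS4class{BinaryMask} restricting the voxels.
#' @param nSphere number of half-sphere search directions.
#' @return data.frame peak table (voxel, dx, dy, dz, id, amplitude).
#' @export
extractPeaks <- function(shField, relThreshold = 0.1, minSeparation = 25,
                         mask = NULL, nSphere = 362L) {
  dm <- dim(shField@coefficients)[1:3]
  nc <- dim(shField@coefficients)[4]
  coefs <- matrix(shField@coefficients, ncol = nc)
  vox <- if (is.null(mask)) which(!is.na(coefs[, 1])) else
    intersect(which(mask@data), which(!is.na(coefs[, 1])))
  dirs <- sphereDirections(nSphere, hemisphere = TRUE)
  B <- shBasis(dirs, shField@lmax)
  nb <- sphereNeighbors(dirs, k = 6L)
  minSepCos <- cos(minSeparation * pi / 180)
  out <- vector("list", length(vox))
  for (ii in seq_along(vox)) {
    cf <- coefs[vox[ii], ]
    if (all(cf == 0)) next
    amp <- as.numeric(B %*% cf)
    mx <- max(amp)
    if (mx <= 0) next
    cand <- which(vapply(seq_along(amp), function(i)
      amp[i] >= max(amp[nb[[i]]]), logical(1)) & amp >= relThreshold * mx)
    if (!length(cand)) next
    ## refine each candidate on the sphere, then greedy separation filter
    ref <- t(vapply(cand, function(i) refinePeak(dirs[i, ], cf, shField@lmax),
                    numeric(4)))
    ord <- order(ref[, 4], decreasing = TRUE)
    kept <- matrix(numeric(0), 0, 4)
    for (r in ord) {
      d <- ref[r, 1:3]
      if (nrow(kept) &&
          any(abs(kept[, 1:3, drop = FALSE] %*% d) > minSepCos)) next
      if (ref[r, 4] < relThreshold * ref[ord[1], 4]) next
      kept <- rbind(kept, ref[r, ])
    }
    if (!nrow(kept)) next
    out[[ii]] <- data.frame(voxel = vox[ii], dx = kept[, 1], dy = kept[, 2],
                            dz = kept[, 3], id = seq_len(nrow(kept)),
                            amplitude = kept[, 4])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(voxel = integer(), dx = numeric(), dy = numeric(),
                      dz = numeric(), id = integer(), amplitude = numeric())
  rownames(res) <- NULL
  res
}

## k-nearest-neighbor lists on a direction set (angular metric, antipodally
## folded).
sphereNeighbors <- function(dirs, k = 6L) {
  ca <- abs(dirs %*% t(dirs))
  lapply(seq_len(nrow(dirs)), function(i) {
    ord <- order(ca[i, ], decreasing = TRUE)
    setdiff(ord, i)[seq_len(k)]
  })
}

## Local maximization of the SH function from a starting direction.
refinePeak <- function(d0, cf, lmax) {
  f <- function(ang) {
    d <- c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[1]))
    -as.numeric(shBasis(matrix(d, 1, 3), lmax) %*% cf)
  }
  a0 <- c(acos(pmin(1, pmax(-1, d0[3]))), atan2(d0[2], d0[1]))
  o <- optim(a0, f, method = "Nelder-Mead",
             control = list(maxit = 60, reltol = 1e-8))
  d <- c(sin(o$par[1]) * cos(o$par[2]), sin(o$par[1]) * sin(o$par[2]),
         cos(o$par[1]))
  if (d[3] < 0) d <- -d                 # half-sphere representative
  c(d, -o$value)
}
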