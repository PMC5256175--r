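## Construction of the sparse forward operator A of the convex fit
## argmin_{x >= 0} || A x - y ||^2: one intracellular (Stick) column per
## streamline weighted by in-voxel segment length, one hindered (Zeppelin)
## column per (voxel, FOD peak), and two isotropic (Ball) columns per voxel.
## Rows are stacked per voxel over all volumes of the scheme; b0 rows carry
## attenuation 1 scaled by the same geometric weights.

#' Build the Stick-Zeppelin-Ball signal dictionary
#'
#' @param tg a \linkS4class{Tractogram} (or \linkS4class{Bundle}); may be
#'   empty, in which case only hindered/isotropic columns are produced.
#' @param peaks peak table (see \code{\link{extractPeaks}}) giving the
#'   hindered directions per voxel; rows outside the mask are ignored.
#' @param scheme an \linkS4class{AcquisitionScheme}.
#' @param params \linkS4class{CompartmentParams}.
#' @param mask \linkS4class{BinaryMask} of the voxels to model (typically
#'   white matter restricted to voxels with positive b0).
#' @param step streamline tracing step in mm (default 0.5).
#' @return A \linkS4class{SignalDictionary}.
#' @export
buildDictionary <- function(tg, peaks, scheme, params, mask, step = 0.5) {
  dm <- dim(mask@data)
  voxels <- which(mask@data)
  block <- integer(prod(dm))
  block[voxels] <- seq_along(voxels)     # voxel linear index -> row block
  nvol <- length(scheme@bvals)
  dw <- dwIndices(scheme)
  bdw <- scheme@bvals[dw]
  G <- scheme@bvecs[dw, , drop = FALSE]
  nfib <- length(tg@streamlines)

  iList <- list(); xList <- list(); jList <- list()
  put <- function(rows, vals, col) {
    n <- length(iList) + 1L
    iList[[n]] <<- rows; xList[[n]] <<- vals
    jList[[n]] <<- rep.int(col, length(rows))
  }
  rowsFor <- function(blk) {             # all-volume rows of one voxel block
    (blk - 1L) * nvol + seq_len(nvol)
  }

  ## --- intracellular columns -------------------------------------------
  for (fi in seq_len(nfib)) {
    seg <- traceSegments(tg@streamlines[[fi]], mask@affine, dm, step = step)
    if (nrow(seg)) seg <- seg[block[seg$voxel] > 0L, , drop = FALSE]
    if (!nrow(seg)) next
    t3 <- as.matrix(seg[, c("tx", "ty", "tz")])
    ct <- G %*% t(t3)                               # ndw x nseg
    atten <- exp(-(bdw * params@dParStick) * ct^2)
    wa <- t(atten) * seg$length                     # nseg x ndw
    grp <- factor(seg$voxel)
    prof <- rowsum(wa, grp)                         # nvoxgrp x ndw
    lenSum <- rowsum(seg$length, grp)[, 1]
    vxs <- as.integer(levels(grp))
    blks <- block[vxs]
    full <- matrix(0, length(vxs), nvol)
    full[, dw] <- prof
    full[, scheme@b0Indices] <- lenSum
    rows <- as.integer(t(outer(blks, seq_len(nvol),
                               function(b, v) (b - 1L) * nvol + v)))
    put(rows, as.numeric(t(full)), fi)
  }
  fibCols <- seq_len(nfib)

  ## --- hindered columns -------------------------------------------------
  colId <- nfib
  hinRows <- data.frame(voxel = integer(), param = numeric())
  if (!is.null(peaks) && nrow(peaks)) {
    pk <- peaks[block[peaks$voxel] > 0L, , drop = FALSE]
    if (is.null(pk$id)) pk$id <- ave(pk$voxel, pk$voxel, FUN = seq_along)
    for (r in seq_len(nrow(pk))) {
      v <- c(pk$dx[r], pk$dy[r], pk$dz[r])
      full <- numeric(nvol)
      ct <- as.numeric(G %*% v)
      full[dw] <- exp(-bdw * (params@dPerpZeppelin +
                     (params@dParZeppelin - params@dPerpZeppelin) * ct^2))
      full[scheme@b0Indices] <- 1
      colId <- colId + 1L
      put(rowsFor(block[pk$voxel[r]]), full, colId)
    }
    hinRows <- data.frame(voxel = pk$voxel, param = as.numeric(pk$id))
  }

  ## --- isotropic columns ------------------------------------------------
  isoProfiles <- lapply(seq_along(params@dIso), function(k) {
    full <- numeric(nvol)
    full[dw] <- exp(-bdw * params@dIso[k])
    full[scheme@b0Indices] <- 1
    full
  })
  isoVox <- integer(0); isoPar <- integer(0)
  for (k in seq_along(params@dIso)) {
    for (b in seq_along(voxels)) {
      colId <- colId + 1L
      put(rowsFor(b), isoProfiles[[k]], colId)
    }
    isoVox <- c(isoVox, voxels)
    isoPar <- c(isoPar, rep.int(k, length(voxels)))
  }

  A <- Matrix::sparseMatrix(i = unlist(iList), j = unlist(jList),
                            x = unlist(xList),
                            dims = c(length(voxels) * nvol, colId))
  columnMap <- rbind(
    data.frame(kind = rep("intracellular", nfib),
               fiber = fibCols,
               voxel = rep(NA_integer_, nfib),
               param = rep(NA_real_, nfib)),
    data.frame(kind = rep("hindered", nrow(hinRows)),
               fiber = rep(NA_integer_, nrow(hinRows)),
               voxel = hinRows$voxel,
               param = hinRows$param),
    data.frame(kind = rep("isotropic", length(isoVox)),
               fiber = rep(NA_integer_, length(isoVox)),
               voxel = isoVox,
               param = as.numeric(isoPar)))
  new("SignalDictionary", matrix = A, columnMap = columnMap,
      voxels = as.integer(voxels), scheme = scheme,
      gridDim = as.integer(dm))
}
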