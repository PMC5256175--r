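## b0 normalization, the non-negative least-squares fit of the dictionary by
## forward-backward FISTA, and the NRMSE of the resulting signal estimator.

#' NormalizedSignal: b0-normalized signal vector over (voxel, volume) pairs
#'
#' @slot y normalized signal stacked per voxel over all volumes, matching
#'   the row layout of a \linkS4class{SignalDictionary} built on
#'   \code{mask}.
#' @slot b0Reference per-voxel mean b0 value used for normalization.
#' @slot voxels 1-based linear indices of the included voxels.
#' @slot mask effective analysis mask (input mask minus voxels with
#'   non-positive b0).
#' @slot nExcluded number of in-mask voxels dropped for b0 <= 0.
#' @export
setClass("NormalizedSignal",
  representation(y = "numeric", b0Reference = "numeric", voxels = "integer",
                 mask = "BinaryMask", nExcluded = "integer"))

setMethod("show", "NormalizedSignal", function(object) {
  cat("NormalizedSignal:", length(object@voxels), "voxels x",
      length(object@y) / max(1L, length(object@voxels)), "volumes;",
      object@nExcluded, "voxel(s) excluded for b0 <= 0\n")
})

#' WeightVector: non-negative dictionary weights with solver diagnostics
#'
#' @slot x per-column weights (all >= 0).
#' @slot objectiveTrace objective value 0.5 * ||Ax - y||^2 per iteration.
#' @slot nIter iterations run.
#' @slot converged TRUE when the relative objective change fell below the
#'   tolerance before the iteration cap.
#' @export
setClass("WeightVector",
  representation(x = "numeric", objectiveTrace = "numeric",
                 nIter = "integer", converged = "logical"))

setMethod("show", "WeightVector", function(object) {
  cat("WeightVector:", length(object@x), "weights,",
      sum(object@x > 0), "nonzero;", object@nIter, "iterations,",
      if (object@converged) "converged" else "iteration cap reached", "\n")
})

#' FitResult: predicted signal and NRMSE map
#'
#' @slot sHat predicted signal on the original scale, stacked like the
#'   normalized signal.
#' @slot nrmse 3D NRMSE map (NA outside the analysis mask).
#' @slot weights the \linkS4class{WeightVector}.
#' @slot voxels voxels covered (matching the dictionary).
#' @export
setClass("FitResult",
  representation(sHat = "numeric", nrmse = "array", weights = "WeightVector",
                 voxels = "integer"))

setMethod("show", "FitResult", function(object) {
  cat("FitResult:", length(object@voxels), "voxels; mean NRMSE",
      signif(mean(object@nrmse, na.rm = TRUE), 4), "\n")
})

#' Normalize diffusion data by the b0 image
#'
#' Divides every volume by the per-voxel mean over b0 volumes. In-mask
#' voxels with non-positive b0 are excluded (not zero-filled) and counted.
#'
#' @param dwi a \linkS4class{DWIVolume}.
#' @param mask \linkS4class{BinaryMask} of voxels to include.
#' @return A \linkS4class{NormalizedSignal}.
#' @export
normalizeSignal <- function(dwi, mask) {
  stopifnot(all(dim(mask@data) == dim(dwi@data)[1:3]))
  dm <- dim(dwi@data)[1:3]
  nvol <- dim(dwi@data)[4]
  vox <- which(mask@data)
  sig <- matrix(dwi@data, ncol = nvol)[vox, , drop = FALSE]
  b0 <- rowMeans(sig[, b0Indices(dwi@scheme), drop = FALSE])
  bad <- b0 <= 0 | !is.finite(b0)
  if (any(bad))
    warning(sum(bad), " in-mask voxel(s) with b0 <= 0 excluded from the fit")
  vox <- vox[!bad]; sig <- sig[!bad, , drop = FALSE]; b0 <- b0[!bad]
  y <- as.numeric(t(sig / b0))           # per voxel, all volumes contiguous
  eff <- array(FALSE, dm); eff[vox] <- TRUE
  new("NormalizedSignal", y = y, b0Reference = b0, voxels = as.integer(vox),
      mask = new("BinaryMask", data = eff, affine = dwi@affine),
      nExcluded = as.integer(sum(bad)))
}

#' Solve the non-negative least-squares problem by FISTA
#'
#' Minimizes 0.5 * ||A x - y||^2 subject to x >= 0 with the
#' forward-backward fast iterative shrinkage-thresholding algorithm: step
#' size 1/L with L the largest eigenvalue of A'A estimated by power
#' iteration, projection onto the non-negative orthant, and a monotone
#' restart whenever the objective would increase. Stops after
#' \code{maxIter} iterations or when the relative objective change drops
#' below \code{relTol}.
#'
#' Columns are l2-normalized internally (the usual dictionary
#' preconditioning; non-negativity is preserved) and the weights rescaled
#' back on return, which greatly improves the conditioning of dictionaries
#' whose columns differ by orders of magnitude in norm.
#'
#' @param A a \linkS4class{SignalDictionary} or a (sparse) matrix.
#' @param y a \linkS4class{NormalizedSignal} or numeric vector.
#' @param maxIter iteration cap (default 500).
#' @param relTol relative objective-change tolerance (default 1e-4).
#' @param normalizeColumns precondition by column l2 norms (default TRUE).
#' @return A \linkS4class{WeightVector}.
#' @export
solveNNLS <- function(A, y, maxIter = 500L, relTol = 1e-4,
                      normalizeColumns = TRUE) {
  if (is(A, "SignalDictionary")) A <- A@matrix
  if (is(y, "NormalizedSignal")) y <- y@y
  stopifnot(nrow(A) == length(y))
  n <- ncol(A)
  if (all(y == 0) || n == 0L)
    return(new("WeightVector", x = numeric(n), objectiveTrace = 0,
               nIter = 0L, converged = TRUE))
  colScale <- rep(1, n)
  if (normalizeColumns) {
    nrm <- sqrt(Matrix::colSums(A^2))
    colScale[nrm > 0] <- 1 / nrm[nrm > 0]
    A <- A %*% Matrix::Diagonal(x = colScale)
  }
  L <- powerIterationL(A)
  stepSize <- 1 / L
  obj <- function(x, r) 0.5 * sum(r^2)
  x <- numeric(n)
  z <- x
  tk <- 1
  rx <- as.numeric(A %*% x) - y
  fx <- obj(x, rx)
  trace <- numeric(maxIter + 1L)
  trace[1] <- fx
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    rz <- as.numeric(A %*% z) - y
    grad <- as.numeric(Matrix::crossprod(A, rz))
    xNew <- pmax(0, z - stepSize * grad)
    rNew <- as.numeric(A %*% xNew) - y
    fNew <- obj(xNew, rNew)
    if (fNew > fx) {                     # monotone restart from x
      z <- x
      tk <- 1
      rz <- rx
      grad <- as.numeric(Matrix::crossprod(A, rz))
      xNew <- pmax(0, z - stepSize * grad)
      rNew <- as.numeric(A %*% xNew) - y
      fNew <- obj(xNew, rNew)
      if (fNew > fx) { it <- it - 1L; break }  # stationary: stop
    }
    tNew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- xNew + ((tk - 1) / tNew) * (xNew - x)
    relChange <- abs(fx - fNew) / max(fx, .Machine$double.xmin)
    x <- xNew; rx <- rNew; fx <- fNew; tk <- tNew
    trace[it + 1L] <- fx
    if (relChange < relTol) { converged <- TRUE; break }
  }
  new("WeightVector", x = x * colScale,
      objectiveTrace = trace[seq_len(it + 1L)],
      nIter = it, converged = converged)
}

## Largest eigenvalue of A'A by power iteration.
powerIterationL <- function(A, iters = 30L) {
  v <- sin(seq_len(ncol(A)))             # deterministic, leaves RNG untouched
  v <- v / sqrt(sum(v^2))
  lam <- 1
  for (i in seq_len(iters)) {
    w <- as.numeric(Matrix::crossprod(A, A %*% v))
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(1)
    v <- w / lam
  }
  ## small safety margin so 1/L remains a valid Lipschitz step
  lam * 1.01
}

#' b0-normalized DW signal as a 4D array
#'
#' Convenience view of a \linkS4class{NormalizedSignal}: the normalized
#' diffusion-weighted volumes on the grid, NA outside the analysis mask
#' (the input expected by \code{\link{csdFit}} for a signal FOD).
#'
#' @param dwi the \linkS4class{DWIVolume}.
#' @param normalized its \linkS4class{NormalizedSignal}.
#' @return 4D array (x, y, z, nDW).
#' @export
normalizedDWArray <- function(dwi, normalized) {
  dm <- dim(dwi@data)[1:3]
  nvol <- dim(dwi@data)[4]
  dw <- dwIndices(dwi@scheme)
  ymat <- matrix(normalized@y, ncol = nvol, byrow = TRUE)
  out <- array(NA_real_, c(dm, length(dw)))
  nxyz <- prod(dm)
  for (k in seq_along(dw))
    out[normalized@voxels + (k - 1L) * nxyz] <- ymat[, dw[k]]
  out
}

#' Predict the signal and compute the NRMSE map
#'
#' The signal estimator is \code{A x} rescaled by the per-voxel b0
#' reference. The per-voxel NRMSE is the root-mean-square error over the
#' diffusion-weighted volumes divided by the voxel's mean measured DW
#' signal (dimensionless; voxels with zero mean signal yield NA).
#'
#' @param A the \linkS4class{SignalDictionary} used in the solve.
#' @param weights the \linkS4class{WeightVector} from \code{\link{solveNNLS}}.
#' @param dwi the measured \linkS4class{DWIVolume}.
#' @param normalized the \linkS4class{NormalizedSignal} used in the solve.
#' @return A \linkS4class{FitResult}.
#' @export
predictFit <- function(A, weights, dwi, normalized) {
  stopifnot(identical(A@voxels, normalized@voxels))
  nvol <- length(A@scheme@bvals)
  yHat <- as.numeric(A@matrix %*% weights@x)
  b0ref <- rep(normalized@b0Reference, each = nvol)
  sHat <- yHat * b0ref
  dm <- dim(dwi@data)[1:3]
  sMeas <- matrix(dwi@data, ncol = nvol)[A@voxels, , drop = FALSE]
  sHatM <- matrix(sHat, ncol = nvol, byrow = TRUE)
  dw <- dwIndices(A@scheme)
  rmse <- sqrt(rowMeans((sMeas[, dw, drop = FALSE] -
                         sHatM[, dw, drop = FALSE])^2))
  denom <- rowMeans(sMeas[, dw, drop = FALSE])
  nrmse <- ifelse(denom > 0, rmse / denom, NA_real_)
  map <- array(NA_real_, dm)
  map[A@voxels] <- nrmse
  new("FitResult", sHat = sHat, nrmse = map, weights = weights,
      voxels = A@voxels)
}
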