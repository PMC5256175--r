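## Residual analysis of the dictionary fit: the element-wise squared error
## signal, its fiber orientation distribution via constrained spherical
## deconvolution with the response estimated from the measured signal, and
## its fractional anisotropy via a log-linear tensor fit.

#' ErrorSignal: squared fit residual per DW direction
#'
#' Element-wise \code{(s - sHat)^2} over the diffusion-weighted volumes
#' (b0 volumes excluded); non-negative by construction.
#'
#' @slot data 4D array (x, y, z, nDW); NA outside the analysis mask.
#' @slot scheme the acquisition scheme (DW subset indexed by dwIndices).
#' @slot affine voxel-to-world transform.
#' @export
setClass("ErrorSignal",
  representation(data = "array", scheme = "AcquisitionScheme",
                 affine = "matrix"))

setMethod("show", "ErrorSignal", function(object) {
  cat("ErrorSignal:", paste(dim(object@data)[1:3], collapse = " x "),
      "grid,", dim(object@data)[4], "DW directions; max",
      signif(max(object@data, na.rm = TRUE), 4), "\n")
})

#' TensorFitMaps: diffusion-tensor fit summary
#'
#' @slot fa 3D fractional anisotropy map in [0, 1] (NA where undefined).
#' @slot evals 4D array (x, y, z, 3) of eigenvalues sorted descending.
#' @slot e1 4D array (x, y, z, 3): principal eigenvector.
#' @export
setClass("TensorFitMaps",
  representation(fa = "array", evals = "array", e1 = "array"))

setMethod("show", "TensorFitMaps", function(object) {
  cat("TensorFitMaps:", paste(dim(object@fa), collapse = " x "),
      "grid; median FA", signif(median(object@fa, na.rm = TRUE), 3), "\n")
})

#' Compute the squared error signal of a fit
#'
#' @param dwi measured \linkS4class{DWIVolume}.
#' @param fit \linkS4class{FitResult} from \code{\link{predictFit}}.
#' @param residual "squared" (default) or "absolute" residual, for
#'   sensitivity checks.
#' @return An \linkS4class{ErrorSignal}.
#' @export
computeErrorSignal <- function(dwi, fit, residual = c("squared", "absolute")) {
  residual <- match.arg(residual)
  dm <- dim(dwi@data)[1:3]
  nvol <- dim(dwi@data)[4]
  dw <- dwIndices(dwi@scheme)
  sMeas <- matrix(dwi@data, ncol = nvol)[fit@voxels, dw, drop = FALSE]
  sHatM <- matrix(fit@sHat, ncol = nvol, byrow = TRUE)[, dw, drop = FALSE]
  d <- sMeas - sHatM
  err <- if (residual == "squared") d^2 else abs(d)
  out <- array(NA_real_, c(dm, length(dw)))
  nxyz <- prod(dm)
  for (k in seq_along(dw))
    out[fit@voxels + (k - 1L) * nxyz] <- err[, k]
  new("ErrorSignal", data = out, scheme = dwi@scheme, affine = dwi@affine)
}

## Log-linear tensor core: rows of S are voxels, columns DW measurements.
## Fits log(S / s0ref) = -b g' D g (6 parameters); eps guards the log.
## s0ref is the per-voxel reference amplitude: the known b0 when available,
## otherwise the per-voxel maximum DW value (a b0-free signal on a single
## shell cannot identify an S0 intercept, which is collinear with the
## tensor trace; the max reference keeps the fit scale-invariant and exact
## for noiseless single-compartment profiles). Returns list(evals nvox x 3
## descending, e1 nvox x 3, fa length nvox).
tensorCore <- function(S, bdw, G, s0ref = NULL, eps = 1e-10) {
  if (is.null(s0ref)) s0ref <- apply(S, 1, max)
  X <- cbind(-bdw * G[, 1]^2, -bdw * G[, 2]^2, -bdw * G[, 3]^2,
             -2 * bdw * G[, 1] * G[, 2], -2 * bdw * G[, 1] * G[, 3],
             -2 * bdw * G[, 2] * G[, 3])
  Sn <- S / pmax(s0ref, eps)
  coef <- qr.coef(qr(X), t(log(pmax(Sn, eps))))   # 6 x nvox
  coef <- matrix(coef, nrow = 6)
  nv <- ncol(coef)
  evals <- matrix(NA_real_, nv, 3)
  e1 <- matrix(NA_real_, nv, 3)
  fa <- rep(NA_real_, nv)
  for (v in seq_len(nv)) {
    d <- coef[, v]
    if (anyNA(d)) next
    D <- matrix(c(d[1], d[4], d[5],
                  d[4], d[2], d[6],
                  d[5], d[6], d[3]), 3, 3)
    eg <- eigen(D, symmetric = TRUE)
    evals[v, ] <- eg$values
    e1[v, ] <- eg$vectors[, 1]
    fa[v] <- faFromEigenvalues(eg$values)
  }
  list(evals = evals, e1 = e1, fa = fa)
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' Negative eigenvalues are clipped to zero first; an all-zero tensor gives
#' FA = 0.
#'
#' @param evals numeric vector of 3 eigenvalues.
#' @return FA in [0, 1].
#' @export
#' @examples
#' faFromEigenvalues(c(1, 0, 0))   # 1
faFromEigenvalues <- function(evals) {
  lam <- pmax(evals, 0)
  if (sum(lam^2) == 0) return(0)
  min(1, sqrt(1.5 * sum((lam - mean(lam))^2) / sum(lam^2)))
}

#' Diffusion-tensor fit with FA map
#'
#' Standard log-linear least-squares fit. The error signal carries no b0
#' sample, and on a single-shell scheme an S0 intercept is collinear with
#' the tensor trace, so the per-voxel reference amplitude is taken as the
#' maximum DW value instead (making the FA invariant to global scaling of
#' the input); a small epsilon guards the logarithm. Negative eigenvalues
#' are clipped to zero before the FA is formed.
#'
#' @param signal 4D array over DW directions (e.g. an
#'   \linkS4class{ErrorSignal}'s data) or an \linkS4class{ErrorSignal}.
#' @param scheme acquisition scheme; the 4th dimension must match its DW
#'   subset.
#' @param mask optional \linkS4class{BinaryMask}.
#' @return A \linkS4class{TensorFitMaps}; voxels that are all zero (or all
#'   NA) get FA = NA.
#' @export
fitTensorFA <- function(signal, scheme = NULL, mask = NULL) {
  if (is(signal, "ErrorSignal")) {
    scheme <- signal@scheme
    signal <- signal@data
  }
  stopifnot(!is.null(scheme))
  dw <- dwIndices(scheme)
  if (length(dw) < 7L) stop("tensor fit needs at least 7 DW directions")
  stopifnot(dim(signal)[4] == length(dw))
  dm <- dim(signal)[1:3]
  S <- matrix(signal, ncol = length(dw))
  vox <- which(rowSums(is.na(S)) == 0 & rowSums(S) > 0)
  if (!is.null(mask)) vox <- intersect(vox, which(mask@data))
  fa <- array(NA_real_, dm)
  evals <- array(NA_real_, c(dm, 3))
  e1 <- array(NA_real_, c(dm, 3))
  if (length(vox)) {
    res <- tensorCore(S[vox, , drop = FALSE], scheme@bvals[dw],
                      scheme@bvecs[dw, , drop = FALSE])
    nxyz <- prod(dm)
    fa[vox] <- res$fa
    for (k in 1:3) {
      evals[vox + (k - 1L) * nxyz] <- res$evals[, k]
      e1[vox + (k - 1L) * nxyz] <- res$e1[, k]
    }
  }
  new("TensorFitMaps", fa = fa, evals = evals, e1 = e1)
}

#' Estimate the single-fiber response function from the data
#'
#' Single-pass selection: tensor-fit all in-mask voxels, take those with
#' FA above \code{faMin} (relaxing the threshold in 0.05 steps with a
#' warning when fewer than \code{minVoxels} qualify), rotate each voxel's
#' normalized signal so its principal eigenvector maps to z, fit zonal
#' (m = 0) harmonics, and average the coefficients.
#'
#' @param dwi \linkS4class{DWIVolume}.
#' @param wmMask \linkS4class{BinaryMask}.
#' @param faMin initial FA threshold (default 0.7).
#' @param nVoxels use at most this many of the highest-FA voxels (300).
#' @param minVoxels relax the threshold until this many qualify (default 30).
#' @param lmax maximum even SH order of the response (default 8).
#' @return A \linkS4class{ResponseFunction}.
#' @export
estimateResponse <- function(dwi, wmMask, faMin = 0.7, nVoxels = 300L,
                             minVoxels = 30L, lmax = 8L) {
  nvol <- dim(dwi@data)[4]
  dw <- dwIndices(dwi@scheme)
  vox <- which(wmMask@data)
  sig <- matrix(dwi@data, ncol = nvol)[vox, , drop = FALSE]
  b0 <- rowMeans(sig[, b0Indices(dwi@scheme), drop = FALSE])
  ok <- b0 > 0
  vox <- vox[ok]; sig <- sig[ok, , drop = FALSE]; b0 <- b0[ok]
  Snorm <- sig[, dw, drop = FALSE] / b0
  res <- tensorCore(Snorm, dwi@scheme@bvals[dw],
                    dwi@scheme@bvecs[dw, , drop = FALSE],
                    s0ref = rep(1, nrow(Snorm)))   # already b0-normalized
  thr <- faMin
  repeat {
    sel <- which(!is.na(res$fa) & res$fa >= thr)
    if (length(sel) >= minVoxels || thr <= 0.2) break
    thr <- thr - 0.05
    warning(sprintf("fewer than %d voxels with FA >= %.2f; relaxing to %.2f",
                    minVoxels, thr + 0.05, thr))
  }
  if (length(sel) < minVoxels) {         # degenerate data: take the top-FA
    warning("threshold relaxation exhausted; falling back to the ",
            minVoxels, " highest-FA voxels")
    sel <- order(res$fa, decreasing = TRUE, na.last = NA)
  }
  if (!length(sel)) stop("no voxels available for response estimation")
  sel <- sel[order(res$fa[sel], decreasing = TRUE)][seq_len(
    min(nVoxels, length(sel)))]
  G <- dwi@scheme@bvecs[dw, , drop = FALSE]
  ez <- c(0, 0, 1)
  rls <- vapply(sel, function(v) {
    R <- rotationBetween(res$e1[v, ], ez)
    shFitZonal(G %*% t(R), Snorm[v, ], lmax)
  }, numeric(length(seq(0, lmax, 2))))
  new("ResponseFunction", rl = rowMeans(matrix(rls, ncol = length(sel))),
      lmax = as.integer(lmax))
}

#' Constrained spherical deconvolution of a signal field
#'
#' Per voxel, deconvolves the DW signal profile with an axially symmetric
#' response to obtain FOD coefficients, enforcing non-negativity on a dense
#' constraint sphere by iteratively re-weighted regularized least squares:
#' directions whose current FOD amplitude falls below a threshold
#' (\code{tau} times the mean amplitude of the initial low-order fit) are
#' penalized until the active set stabilizes.
#'
#' @param signal 4D array over DW directions, or an
#'   \linkS4class{ErrorSignal}.
#' @param response \linkS4class{ResponseFunction}.
#' @param scheme acquisition scheme (taken from an ErrorSignal input).
#' @param affine voxel-to-world affine (taken from an ErrorSignal input).
#' @param lmax maximum even order of the FOD (default 8).
#' @param nIter maximum constraint iterations per voxel (default 50).
#' @param tau amplitude threshold fraction (default 0.1).
#' @param lambda non-negativity constraint weight (default 1). Small values favor data fidelity (forward projection of the FOD reproduces the band-limited signal), large values suppress negative FOD lobes harder; the two goals trade off at a fixed lmax.
#' @param nConstraint constraint-sphere size (default 300).
#' @param mask optional \linkS4class{BinaryMask}.
#' @return An \linkS4class{SHField}; all-zero voxels get all-zero
#'   coefficients.
#' @export
csdFit <- function(signal, response, scheme = NULL, affine = NULL,
                   lmax = 8L, nIter = 50L, tau = 0.1, lambda = 1,
                   nConstraint = 300L, mask = NULL) {
  if (is(signal, "ErrorSignal")) {
    scheme <- signal@scheme
    if (is.null(affine)) affine <- signal@affine
    signal <- signal@data
  }
  stopifnot(!is.null(scheme))
  if (is.null(affine)) affine <- diag(4)
  dw <- dwIndices(scheme)
  stopifnot(dim(signal)[4] == length(dw))
  dm <- dim(signal)[1:3]
  G <- scheme@bvecs[dw, , drop = FALSE]
  rl <- response@rl
  lr <- seq(0, response@lmax, 2)
  lneed <- seq(0, lmax, 2)
  rlFull <- numeric(length(lneed))
  rlFull[match(intersect(lneed, lr), lneed)] <- rl[match(intersect(lneed, lr), lr)]
  fconv <- shConvolutionFactors(rlFull, lmax)
  B <- shBasis(G, lmax)
  C <- B * rep(fconv, each = nrow(B))
  CtC <- crossprod(C)
  nc <- ncol(C)
  Bc <- shBasis(symmetricSphere(nConstraint), lmax)
  ## initial fit restricted to order 4 (or lmax if lower), lightly damped
  lowCols <- which(shIndexTable(lmax)[, "l"] <= min(4L, lmax))
  Clow <- C[, lowCols, drop = FALSE]
  lowSolve <- solve(crossprod(Clow) + 1e-8 * diag(length(lowCols)),
                    t(Clow))
  S <- matrix(signal, ncol = length(dw))
  vox <- which(rowSums(is.na(S)) == 0)
  if (!is.null(mask)) vox <- intersect(vox, which(mask@data))
  coefs <- array(NA_real_, c(dm, nc))
  nxyz <- prod(dm)
  lam2 <- lambda^2
  for (v in vox) {
    s <- S[v, ]
    if (all(s == 0)) { coefs[v + (seq_len(nc) - 1L) * nxyz] <- 0; next }
    Cts <- crossprod(C, s)
    x <- numeric(nc)
    x[lowCols] <- lowSolve %*% s
    tauVal <- tau * mean(Bc %*% x)
    negPrev <- NULL
    for (it in seq_len(nIter)) {
      amp <- Bc %*% x
      neg <- which(amp < tauVal)
      if (!is.null(negPrev) && identical(neg, negPrev)) break
      if (length(neg) >= nrow(Bc) - nc) neg <- order(amp)[seq_len(nrow(Bc) - nc)]
      Bn <- Bc[neg, , drop = FALSE]
      x <- tryCatch(
        as.numeric(solve(CtC + lam2 * crossprod(Bn), Cts)),
        error = function(e) x)
      negPrev <- neg
    }
    coefs[v + (seq_len(nc) - 1L) * nxyz] <- x
  }
  new("SHField", coefficients = coefs, lmax = as.integer(lmax),
      basis = shBasisTag, affine = affine)
}

#' SH field of a 4D DW signal (plain least-squares fit)
#'
#' Utility to express a measured signal in the SH basis (e.g. for FOD peak
#' extraction via CSD of the measured data use \code{\link{csdFit}}).
#'
#' @inheritParams csdFit
#' @return An \linkS4class{SHField}.
#' @export
shFitSignal <- function(signal, scheme = NULL, affine = diag(4), lmax = 8L,
                        mask = NULL) {
  if (is(signal, "ErrorSignal")) {
    scheme <- signal@scheme; affine <- signal@affine; signal <- signal@data
  }
  dw <- dwIndices(scheme)
  stopifnot(dim(signal)[4] == length(dw))
  dm <- dim(signal)[1:3]
  B <- shBasis(scheme@bvecs[dw, , drop = FALSE], lmax)
  proj <- solve(crossprod(B) + 1e-10 * diag(ncol(B)), t(B))
  S <- matrix(signal, ncol = length(dw))
  vox <- which(rowSums(is.na(S)) == 0)
  if (!is.null(mask)) vox <- intersect(vox, which(mask@data))
  coefs <- array(NA_real_, c(dm, ncol(B)))
  nxyz <- prod(dm)
  cf <- proj %*% t(S[vox, , drop = FALSE])     # nc x nvox
  for (k in seq_len(ncol(B)))
    coefs[vox + (k - 1L) * nxyz] <- cf[k, ]
  new("SHField", coefficients = coefs, lmax = as.integer(lmax),
      basis = shBasisTag, affine = affine)
}
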