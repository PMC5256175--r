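## Real, symmetric (even-order) spherical harmonics, the representation used
## for fiber orientation distributions and axially symmetric response
## functions.  Basis convention ("tractoval-real-even"): coefficients are
## ordered l = 0, 2, ..., lmax and within each l by m = -l..l, with
##   m < 0 : sqrt(2) * Nlm * P_l^|m|(cos theta) * sin(|m| phi)
##   m = 0 :           Nl0 * P_l^0(cos theta)
##   m > 0 : sqrt(2) * Nlm * P_l^m(cos theta)  * cos(m phi)
## where Nlm P_l^m is the orthonormalized associated Legendre function
## (Condon-Shortley phase included).  The basis is orthonormal on the sphere.

shBasisTag <- "tractoval-real-even"

#' Number of even-order SH coefficients up to lmax
#' @param lmax maximum (even) harmonic order.
#' @return integer, (lmax+1)(lmax+2)/2.
#' @export
shCount <- function(lmax) as.integer((lmax + 1) * (lmax + 2) / 2)

## (l, m) index table for the even basis.
shIndexTable <- function(lmax) {
  ls <- seq(0, lmax, by = 2)
  do.call(rbind, lapply(ls, function(l) cbind(l = l, m = seq(-l, l))))
}

## Orthonormalized associated Legendre P-bar_l^m(x) for all l = 0..lmax,
## m = 0..l, vectorized over x.  Returns list [[l+1]][[m+1]] of vectors.
normLegendre <- function(lmax, x) {
  s <- sqrt(pmax(0, 1 - x^2))
  P <- vector("list", lmax + 1)
  for (l in 0:lmax) P[[l + 1]] <- vector("list", l + 1)
  P[[1]][[1]] <- rep(sqrt(1 / (4 * pi)), length(x))
  for (m in seq_len(lmax)) {                       # diagonal: P_m^m
    P[[m + 1]][[m + 1]] <- -sqrt((2 * m + 1) / (2 * m)) * s * P[[m]][[m]]
  }
  for (m in 0:(lmax - 1)) {                        # first off-diagonal
    P[[m + 2]][[m + 1]] <- sqrt(2 * m + 3) * x * P[[m + 1]][[m + 1]]
  }
  for (m in 0:lmax) {
    if (m + 2 > lmax) next
    for (l in (m + 2):lmax) {
      a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
      b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
      P[[l + 1]][[m + 1]] <- a * (x * P[[l]][[m + 1]] - b * P[[l - 1]][[m + 1]])
    }
  }
  P
}

#' Real even spherical-harmonic design matrix
#'
#' Evaluates the real symmetric SH basis at a set of unit directions.
#'
#' @param dirs n x 3 matrix of unit vectors.
#' @param lmax maximum even order (default 8, giving 45 columns).
#' @return n x shCount(lmax) design matrix.
#' @export
#' @examples
#' B <- shBasis(symmetricSphere(60), lmax = 4)
#' dim(B)
shBasis <- function(dirs, lmax = 8L) {
  dirs <- matrix(dirs, ncol = 3)
  ct <- pmin(1, pmax(-1, dirs[, 3]))
  phi <- atan2(dirs[, 2], dirs[, 1])
  P <- normLegendre(lmax, ct)
  tab <- shIndexTable(lmax)
  B <- matrix(0, nrow(dirs), nrow(tab))
  for (k in seq_len(nrow(tab))) {
    l <- tab[k, "l"]; m <- tab[k, "m"]
    if (m == 0) {
      B[, k] <- P[[l + 1]][[1]]
    } else if (m > 0) {
      B[, k] <- sqrt(2) * P[[l + 1]][[m + 1]] * cos(m * phi)
    } else {
      B[, k] <- sqrt(2) * P[[l + 1]][[-m + 1]] * sin(-m * phi)
    }
  }
  B
}

## m = 0 column positions within the even basis, one per order l.
shZonalIndex <- function(lmax) {
  tab <- shIndexTable(lmax)
  which(tab[, "m"] == 0)
}

## Per-coefficient convolution factors sqrt(4 pi / (2l+1)) * r_l for an
## axially symmetric kernel with zonal (m = 0) coefficients r_l.  Funk-Hecke:
## convolving an SH field with the kernel multiplies coefficient (l, m) by
## this factor.
shConvolutionFactors <- function(rl, lmax) {
  ls <- seq(0, lmax, by = 2)
  stopifnot(length(rl) == length(ls))
  tab <- shIndexTable(lmax)
  f <- sqrt(4 * pi / (2 * tab[, "l"] + 1))
  rlPer <- rl[match(tab[, "l"], ls)]
  f * rlPer
}

#' Fit zonal (m = 0) SH coefficients of an axially symmetric profile
#'
#' Least-squares projection of samples of a z-axially-symmetric function onto
#' the m = 0 even harmonics; used to represent single-fiber response
#' functions.
#'
#' @param dirs n x 3 unit directions (in the frame where the symmetry axis is z).
#' @param values function samples at \code{dirs}.
#' @param lmax maximum even order.
#' @return numeric vector of zonal coefficients, one per l in 0,2,...,lmax.
#' @export
shFitZonal <- function(dirs, values, lmax = 8L) {
  B <- shBasis(dirs, lmax)[, shZonalIndex(lmax), drop = FALSE]
  as.numeric(qr.solve(B, values))
}
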