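## Unit-sphere direction sets used for acquisition schemes, FOD evaluation
## and CSD non-negativity constraints.

#' Near-uniform directions on the unit sphere or half-sphere
#'
#' Directions are produced by a Fibonacci (golden-angle) spiral, which is
#' deterministic and close to uniform; for gradient schemes an optional
#' electrostatic-repulsion refinement with antipodal symmetry is applied, the
#' standard construction for diffusion gradient tables.
#'
#' @param n number of directions.
#' @param hemisphere logical; restrict to z >= 0 (antipodal representatives).
#' @param repulsion number of electrostatic-repulsion refinement steps
#'   (0 = plain spiral). Repulsion treats each direction and its antipode as
#'   a charge pair.
#' @return n x 3 matrix of unit vectors.
#' @export
#' @examples
#' g <- sphereDirections(64, hemisphere = TRUE, repulsion = 30)
#' range(sqrt(rowSums(g^2)))
sphereDirections <- function(n, hemisphere = FALSE, repulsion = 0L) {
  stopifnot(n >= 1)
  if (hemisphere) {
    ## spiral over 2n points, keep upper half pattern via z in (0, 1)
    i <- seq_len(n) - 0.5
    z <- i / n                     # (0,1): half-sphere
  } else {
    i <- seq_len(n) - 0.5
    z <- 1 - 2 * i / n             # (-1,1)
  }
  ga <- pi * (3 - sqrt(5))
  th <- ga * (seq_len(n) - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(th), r * sin(th), z)
  if (repulsion > 0L) dirs <- repelDirections(dirs, iters = repulsion)
  if (hemisphere) dirs[dirs[, 3] < 0, ] <- -dirs[dirs[, 3] < 0, , drop = FALSE]
  unitRows(dirs)
}

## Gradient-descent electrostatic repulsion with antipodal symmetry.
repelDirections <- function(dirs, iters = 30L, step = 0.005) {
  n <- nrow(dirs)
  for (it in seq_len(iters)) {
    full <- rbind(dirs, -dirs)
    force <- matrix(0, n, 3)
    for (k in seq_len(n)) {
      d <- sweep(full, 2, dirs[k, ])
      r2 <- rowSums(d^2)
      r2[r2 < 1e-12] <- Inf
      f <- -colSums(d / r2^1.5)    # Coulomb repulsion
    force[k, ] <- f
    }
    ## project onto tangent plane and take a small step
    force <- force - dirs * rowSums(force * dirs)
    dirs <- unitRows(dirs + step * force)
  }
  dirs
}

#' Antipodally symmetric evaluation sphere
#'
#' Returns a set of directions closed under sign flip (each direction and its
#' antipode present), used to evaluate symmetric spherical functions such as
#' FODs. Defaults to ~724 points, giving sub-degree angular resolution at
#' spherical-harmonic order 8.
#'
#' @param n total number of points (rounded up to even).
#' @return n x 3 matrix of unit vectors, the second half the antipodes of the
#'   first.
#' @export
symmetricSphere <- function(n = 724L) {
  half <- sphereDirections(ceiling(n / 2), hemisphere = TRUE)
  rbind(half, -half)
}
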