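## Waypoint-ROI bundle selection with consistent fiber orientation: a
## streamline belongs to a bundle when it traverses both ROIs, and is
## flipped when it meets the second ROI first, so all members run from
## roi1 to roi2.

## First streamline point (after fine resampling) inside a mask, or NA.
firstHit <- function(pts, mask, step = 0.5) {
  L <- cumArcLength(pts)
  if (L[length(L)] <= 0) return(NA_integer_)
  n <- max(2L, as.integer(ceiling(L[length(L)] / step)) + 1L)
  fine <- resamplePolyline(pts, n)
  vox <- pointVoxel(mask@affine, fine, dim(mask@data))
  inside <- !is.na(vox) & mask@data[ifelse(is.na(vox), 1L, vox)]
  if (!any(inside)) NA_integer_ else which(inside)[1]
}

#' Select a bundle by a waypoint-ROI pair
#'
#' Keeps streamlines that intersect both ROIs (any point after 0.5 mm
#' resampling falling inside an ROI voxel counts as a hit) and reverses
#' those that meet \code{roi2} before \code{roi1}, producing a consistently
#' oriented bundle. Selection is idempotent and preserves the parent order.
#'
#' @param tg \linkS4class{Tractogram} (or \linkS4class{Bundle}).
#' @param roi1,roi2 \linkS4class{BinaryMask} waypoint ROIs on the DWI grid.
#' @param name bundle name.
#' @param probabilityMap optional 3D array of per-voxel tract probability;
#'   streamlines whose mean sampled probability falls below
#'   \code{probabilityThreshold} are discarded (refinement hook for users
#'   who supply an atlas map).
#' @param probabilityThreshold threshold for the optional refinement.
#' @return A \linkS4class{Bundle}; empty when nothing qualifies.
#' @export
selectBundle <- function(tg, roi1, roi2, name = "bundle",
                         probabilityMap = NULL, probabilityThreshold = 0) {
  stopifnot(all(dim(roi1@data) == dim(roi2@data)))
  keep <- list()
  ids <- integer()
  origin <- character()
  parentOrigin <- if (is(tg, "Bundle")) tg@origin else
    rep("original", length(tg@streamlines))
  parentIds <- if (is(tg, "Bundle")) tg@sourceIds else
    seq_along(tg@streamlines)
  for (i in seq_along(tg@streamlines)) {
    s <- tg@streamlines[[i]]
    h1 <- firstHit(s, roi1)
    h2 <- firstHit(s, roi2)
    if (is.na(h1) || is.na(h2)) next
    if (h2 < h1) s <- s[rev(seq_len(nrow(s))), , drop = FALSE]
    if (!is.null(probabilityMap)) {
      p <- trilinearSample(probabilityMap, roi1@affine, s)
      if (mean(p, na.rm = TRUE) < probabilityThreshold) next
    }
    keep[[length(keep) + 1L]] <- s
    ids <- c(ids, parentIds[i])
    origin <- c(origin, parentOrigin[i])
  }
  new("Bundle", streamlines = keep, affine = roi1@affine, name = name,
      sourceIds = ids, origin = origin)
}
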