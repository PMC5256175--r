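## S4 containers for the pipeline.  All streamline coordinates are world mm;
## voxel lookups use floor of continuous 0-based voxel indices under the
## half-open convention [i, i+1).

#' @import methods
#' @importFrom Matrix Matrix sparseMatrix
#' @importClassesFrom Matrix Matrix dgCMatrix
NULL

#' AcquisitionScheme: diffusion gradient table
#'
#' Per-volume b-values (s/mm^2) and unit gradient directions, with the
#' positions of the non-diffusion-weighted (b = 0) volumes. Volumes with
#' b < 50 s/mm^2 are treated as b = 0.
#'
#' @slot bvals numeric vector of b-values, one per volume.
#' @slot bvecs numeric matrix (nvolumes x 3) of unit gradient directions;
#'   rows for b0 volumes may be zero.
#' @slot b0Indices integer positions of the b0 volumes.
#' @export
setClass("AcquisitionScheme",
  representation(bvals = "numeric", bvecs = "matrix", b0Indices = "integer"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@bvecs) != length(object@bvals))
      msg <- c(msg, "bvals and bvecs disagree in length")
    if (length(object@b0Indices) < 1L)
      msg <- c(msg, "scheme must contain at least one b0 volume")
    dw <- setdiff(seq_along(object@bvals), object@b0Indices)
    if (length(dw)) {
      nrm <- sqrt(rowSums(object@bvecs[dw, , drop = FALSE]^2))
      if (any(abs(nrm - 1) > 1e-6))
        msg <- c(msg, "non-b0 gradient directions must have unit norm (1e-6)")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct an AcquisitionScheme
#'
#' @param bvals numeric b-values (s/mm^2).
#' @param bvecs nvolumes x 3 matrix of gradient directions; directions are
#'   renormalized when their norm is within 1e-3 of unity.
#' @param b0Threshold b-values below this count as b = 0 (default 50).
#' @return An \linkS4class{AcquisitionScheme}.
#' @export
#' @examples
#' sc <- acquisitionScheme(c(0, 3000, 3000),
#'                         rbind(c(0,0,0), c(1,0,0), c(0,1,0)))
#' b0Indices(sc)
acquisitionScheme <- function(bvals, bvecs, b0Threshold = 50) {
  bvecs <- matrix(as.numeric(bvecs), ncol = 3)
  bvals <- as.numeric(bvals)
  b0 <- which(bvals < b0Threshold)
  if (length(b0) == 0L)
    stop("no b0 volume found (all b-values >= ", b0Threshold, ")")
  if (length(b0) == length(bvals))
    stop("no diffusion-weighted volumes (all b-values below the b0 threshold)")
  dw <- setdiff(seq_along(bvals), b0)
  nrm <- sqrt(rowSums(bvecs[dw, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-3))
    stop("diffusion gradient directions are not unit vectors")
  bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm
  new("AcquisitionScheme", bvals = bvals, bvecs = bvecs,
      b0Indices = as.integer(b0))
}

#' DWIVolume: 4D diffusion-weighted data set
#'
#' @slot data 4D numeric array (x, y, z, volume), non-negative.
#' @slot affine 4x4 voxel-to-world transform (mm).
#' @slot scheme the \linkS4class{AcquisitionScheme}.
#' @export
setClass("DWIVolume",
  representation(data = "array", affine = "matrix",
                 scheme = "AcquisitionScheme"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 4L)
      msg <- c(msg, "data must be a 4D array")
    else if (dim(object@data)[4] != length(object@scheme@bvals))
      msg <- c(msg, "4th data dimension must match the scheme length")
    if (any(object@data < 0, na.rm = TRUE))
      msg <- c(msg, "signal data must be non-negative")
    if (!all(dim(object@affine) == c(4, 4)))
      msg <- c(msg, "affine must be 4x4")
    if (length(msg)) msg else TRUE
  })

#' BinaryMask: 3D boolean volume on a reference grid
#'
#' @slot data logical 3D array.
#' @slot affine 4x4 voxel-to-world transform.
#' @export
setClass("BinaryMask",
  representation(data = "array", affine = "matrix"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) "mask data must be 3D"
    else if (!is.logical(object@data)) "mask data must be logical"
    else TRUE
  })

#' Tractogram: a set of streamlines in world mm
#'
#' @slot streamlines list of Ni x 3 numeric matrices (world mm).
#' @slot affine 4x4 voxel-to-world transform of the reference grid (used to
#'   map world coordinates into voxel indices); identity when unknown.
#' @export
setClass("Tractogram",
  representation(streamlines = "list", affine = "matrix"),
  validity = function(object) {
    for (s in object@streamlines) {
      if (!is.matrix(s) || ncol(s) != 3L)
        return("every streamline must be an N x 3 matrix")
      if (nrow(s) < 2L) return("every streamline needs at least 2 points")
      if (anyNA(s)) return("streamline coordinates must not contain NaN/NA")
    }
    TRUE
  })

#' @describeIn Tractogram-class constructor.
#' @param streamlines list of Ni x 3 matrices (world mm).
#' @param affine reference voxel-to-world affine (default identity).
#' @export
tractogram <- function(streamlines, affine = diag(4)) {
  new("Tractogram", streamlines = lapply(streamlines, function(s)
    matrix(as.numeric(s), ncol = 3)), affine = affine)
}

#' Bundle: an oriented, named subset of a tractogram
#'
#' Member streamlines all intersect the bundle's first waypoint ROI before
#' its second, and run in that direction.
#'
#' @slot name bundle name.
#' @slot sourceIds integer ids into the parent tractogram (NA for fibers
#'   generated by up-sampling).
#' @slot origin character, "original" or "synthetic" per fiber.
#' @export
setClass("Bundle", contains = "Tractogram",
  representation(name = "character", sourceIds = "integer",
                 origin = "character"))

#' SignalDictionary: sparse forward operator of the compartment model
#'
#' Maps non-negative contribution weights (one per streamline, per
#' voxel-level hindered peak, and two isotropic compartments per voxel) to
#' the predicted b0-normalized signal stacked over (voxel, volume) pairs.
#'
#' @slot matrix sparse dgCMatrix, (nvoxels * nvolumes) x ncolumns.
#' @slot columnMap data.frame with columns kind
#'   ("intracellular" | "hindered" | "isotropic"), fiber (streamline id or
#'   NA), voxel (linear voxel index or NA), and param (peak index or
#'   isotropic diffusivity).
#' @slot voxels integer linear indices (1-based) of the voxels covered, in
#'   row-block order.
#' @slot scheme the acquisition scheme defining the per-voxel row block.
#' @slot gridDim integer grid dimensions.
#' @export
setClass("SignalDictionary",
  representation(matrix = "Matrix", columnMap = "data.frame",
                 voxels = "integer", scheme = "AcquisitionScheme",
                 gridDim = "integer"))

#' SHField: per-voxel real even spherical-harmonic coefficients
#'
#' Represents a spherical function per voxel (a fiber orientation
#' distribution of the signal or of the fit error) with real symmetric
#' harmonics up to \code{lmax}.
#'
#' @slot coefficients 4D array (x, y, z, ncoef); NA outside the analysis mask.
#' @slot lmax even maximum order (45 coefficients at lmax 8).
#' @slot basis basis convention tag.
#' @slot affine 4x4 voxel-to-world transform.
#' @export
setClass("SHField",
  representation(coefficients = "array", lmax = "integer",
                 basis = "character", affine = "matrix"),
  validity = function(object) {
    if (length(dim(object@coefficients)) != 4L)
      return("coefficients must be 4D")
    if (dim(object@coefficients)[4] != shCount(object@lmax))
      return(sprintf("expected %d coefficients at lmax %d",
                     shCount(object@lmax), object@lmax))
    TRUE
  })

#' ResponseFunction: zonal harmonics of the single-fiber signal profile
#'
#' @slot rl zonal (m = 0) coefficients, one per even l up to lmax.
#' @slot lmax even maximum order.
#' @export
setClass("ResponseFunction",
  representation(rl = "numeric", lmax = "integer"),
  validity = function(object) {
    if (length(object@rl) != length(seq(0, object@lmax, 2)))
      return("one zonal coefficient per even order required")
    if (object@rl[1] <= 0) return("l = 0 response coefficient must be positive")
    TRUE
  })

#' CompartmentParams: Stick-Zeppelin-Ball diffusivities
#'
#' Defaults follow common white-matter values: stick/zeppelin longitudinal
#' diffusivity 1.7e-3 mm^2/s, zeppelin perpendicular 0.5e-3 mm^2/s, and two
#' isotropic compartments at 1.7e-3 (hindered gray-matter-like) and 3.0e-3
#' (CSF-like) mm^2/s.
#'
#' @slot dParStick stick parallel diffusivity (mm^2/s).
#' @slot dParZeppelin zeppelin parallel diffusivity.
#' @slot dPerpZeppelin zeppelin perpendicular diffusivity.
#' @slot dIso isotropic diffusivities (two compartments).
#' @export
setClass("CompartmentParams",
  representation(dParStick = "numeric", dParZeppelin = "numeric",
                 dPerpZeppelin = "numeric", dIso = "numeric"),
  prototype(dParStick = 1.7e-3, dParZeppelin = 1.7e-3,
            dPerpZeppelin = 0.5e-3, dIso = c(1.7e-3, 3.0e-3)),
  validity = function(object) {
    d <- c(object@dParStick, object@dParZeppelin, object@dPerpZeppelin,
           object@dIso)
    if (any(d <= 0)) return("all diffusivities must be positive")
    if (object@dPerpZeppelin >= object@dParZeppelin)
      return("zeppelin perpendicular diffusivity must be below parallel")
    TRUE
  })

#' @describeIn CompartmentParams-class constructor with standard defaults.
#' @param dParStick,dParZeppelin,dPerpZeppelin,dIso diffusivities in mm^2/s.
#' @export
compartmentParams <- function(dParStick = 1.7e-3, dParZeppelin = 1.7e-3,
                              dPerpZeppelin = 0.5e-3,
                              dIso = c(1.7e-3, 3.0e-3)) {
  new("CompartmentParams", dParStick = dParStick, dParZeppelin = dParZeppelin,
      dPerpZeppelin = dPerpZeppelin, dIso = dIso)
}

#' BundlePCAModel: generative PCA model of fiber-point descriptors
#'
#' @slot center mean 240-vector (80 points x 3 coordinates).
#' @slot basis orthonormal 240 x k component matrix.
#' @slot variances per-component variances (non-increasing).
#' @slot explained per-component explained-variance fractions of the full
#'   (untruncated) variance.
#' @slot nTrain number of training fibers.
#' @export
setClass("BundlePCAModel",
  representation(center = "numeric", basis = "matrix", variances = "numeric",
                 explained = "numeric", nTrain = "integer"),
  validity = function(object) {
    if (any(diff(object@variances) > 1e-8 * max(object@variances, 1e-300)))
      return("component variances must be non-increasing")
    G <- crossprod(object@basis)
    if (max(abs(G - diag(ncol(object@basis)))) > 1e-8)
      return("basis columns must be orthonormal")
    TRUE
  })

#' TractProfile: 100-node along-tract summary of a metric
#'
#' @slot bundle bundle name.
#' @slot metric metric name.
#' @slot values node values (length nNodes).
#' @slot nFibers fibers contributing per node.
#' @slot weightSum sum of fiber weights per node (1 where fibers exist).
#' @export
setClass("TractProfile",
  representation(bundle = "character", metric = "character",
                 values = "numeric", nFibers = "integer",
                 weightSum = "numeric"))

## ---- show methods ---------------------------------------------------------

setMethod("show", "AcquisitionScheme", function(object) {
  cat("AcquisitionScheme:", length(object@bvals), "volumes (",
      length(object@b0Indices), "b0,",
      length(object@bvals) - length(object@b0Indices), "DW ), b =",
      paste(unique(round(object@bvals[-object@b0Indices])), collapse = "/"),
      "s/mm^2\n")
})

setMethod("show", "DWIVolume", function(object) {
  d <- dim(object@data)
  cat("DWIVolume:", paste(d[1:3], collapse = " x "), "grid,", d[4],
      "volumes, voxel size",
      paste(round(sqrt(colSums(object@affine[1:3, 1:3]^2)), 3),
            collapse = " x "), "mm\n")
})

setMethod("show", "Tractogram", function(object) {
  n <- length(object@streamlines)
  npts <- if (n) vapply(object@streamlines, nrow, 1L) else integer()
  cat(class(object), ":", n, "streamlines",
      if (n) sprintf("(%d-%d points)", min(npts), max(npts)) else "", "\n")
})

setMethod("show", "Bundle", function(object) {
  cat("Bundle '", object@name, "': ", length(object@streamlines),
      " streamlines (", sum(object@origin == "original"), " original, ",
      sum(object@origin == "synthetic"), " synthetic)\n", sep = "")
})

setMethod("show", "SignalDictionary", function(object) {
  cat("SignalDictionary:", nrow(object@matrix), "rows x",
      ncol(object@matrix), "columns;",
      length(object@voxels), "voxels;",
      sum(object@columnMap$kind == "intracellular"), "fiber,",
      sum(object@columnMap$kind == "hindered"), "hindered,",
      sum(object@columnMap$kind == "isotropic"), "isotropic columns\n")
})

setMethod("show", "SHField", function(object) {
  d <- dim(object@coefficients)
  cat("SHField: lmax", object@lmax, "(", d[4], "coefficients ) on",
      paste(d[1:3], collapse = " x "), "grid, basis", object@basis, "\n")
})

setMethod("show", "TractProfile", function(object) {
  cat("TractProfile:", object@metric, "along", object@bundle, "-",
      length(object@values), "nodes, mean",
      signif(mean(object@values, na.rm = TRUE), 4), "\n")
})

## ---- accessors ------------------------------------------------------------

#' @rdname AcquisitionScheme-class
#' @param object,x an object.
#' @export
setGeneric("bvals", function(object) standardGeneric("bvals"))
#' @rdname AcquisitionScheme-class
#' @export
setMethod("bvals", "AcquisitionScheme", function(object) object@bvals)

#' @rdname AcquisitionScheme-class
#' @export
setGeneric("bvecs", function(object) standardGeneric("bvecs"))
#' @rdname AcquisitionScheme-class
#' @export
setMethod("bvecs", "AcquisitionScheme", function(object) object@bvecs)

#' @rdname AcquisitionScheme-class
#' @export
setGeneric("b0Indices", function(object) standardGeneric("b0Indices"))
#' @rdname AcquisitionScheme-class
#' @export
setMethod("b0Indices", "AcquisitionScheme", function(object) object@b0Indices)

#' @rdname AcquisitionScheme-class
#' @export
setGeneric("dwIndices", function(object) standardGeneric("dwIndices"))
#' @rdname AcquisitionScheme-class
#' @export
setMethod("dwIndices", "AcquisitionScheme", function(object)
  setdiff(seq_along(object@bvals), object@b0Indices))

#' @rdname Tractogram-class
#' @param object,x an object.
#' @export
setGeneric("streamlines", function(object) standardGeneric("streamlines"))
#' @rdname Tractogram-class
#' @export
setMethod("streamlines", "Tractogram", function(object) object@streamlines)

#' Number of streamlines in a tractogram
#' @param x a Tractogram or Bundle.
#' @export
setMethod("length", "Tractogram", function(x) length(x@streamlines))

#' @rdname SHField-class
#' @param object an object.
#' @export
setGeneric("shCoefficients", function(object) standardGeneric("shCoefficients"))
#' @rdname SHField-class
#' @export
setMethod("shCoefficients", "SHField", function(object) object@coefficients)

#' @rdname TractProfile-class
#' @param object an object.
#' @export
setGeneric("profileValues", function(object) standardGeneric("profileValues"))
#' @rdname TractProfile-class
#' @export
setMethod("profileValues", "TractProfile", function(object) object@values)

#' @rdname BinaryMask-class
#' @param object an object.
#' @export
setGeneric("maskData", function(object) standardGeneric("maskData"))
#' @rdname BinaryMask-class
#' @export
setMethod("maskData", "BinaryMask", function(object) object@data)
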