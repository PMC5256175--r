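## Readers/writers for the standard formats the pipeline touches: NIfTI-1
## volumes (via RNifti), FSL text bvec/bval gradient tables, and TrackVis
## TRK / MRtrix TCK streamline files.  Streamlines are always held in world
## (scanner RAS) mm internally; on-disk conventions are normalized at read.

#' @importFrom RNifti readNifti writeNifti xform
NULL

#' Read a diffusion-weighted data set
#'
#' @param niftiPath 4D NIfTI file.
#' @param bvalPath FSL-style bval file (one row of b-values).
#' @param bvecPath FSL-style bvec file (3 rows of gradient components).
#' @return A \linkS4class{DWIVolume} with a validated
#'   \linkS4class{AcquisitionScheme} (volumes with b < 50 s/mm^2 are b0).
#' @export
readDWI <- function(niftiPath, bvalPath, bvecPath) {
  img <- RNifti::readNifti(niftiPath)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 4L)
    stop("expected a 4D NIfTI volume: ", niftiPath)
  affine <- niftiAffine(img)
  bvals <- scan(bvalPath, quiet = TRUE)
  bvecs <- as.matrix(read.table(bvecPath))
  if (nrow(bvecs) == 3L) bvecs <- t(bvecs)
  if (length(bvals) != dim(data)[4] || nrow(bvecs) != dim(data)[4])
    stop("bval/bvec entries (", length(bvals), "/", nrow(bvecs),
         ") do not match the number of volumes (", dim(data)[4], ")")
  scheme <- acquisitionScheme(bvals, bvecs)
  new("DWIVolume", data = data, affine = affine, scheme = scheme)
}

#' Write a DWIVolume (NIfTI + bval/bvec)
#'
#' @param dwi a \linkS4class{DWIVolume}.
#' @param niftiPath,bvalPath,bvecPath output paths.
#' @export
writeDWI <- function(dwi, niftiPath, bvalPath, bvecPath) {
  img <- RNifti::asNifti(dwi@data)
  img <- RNifti::`sform<-`(img, structure(dwi@affine, code = 2L))
  RNifti::writeNifti(img, niftiPath)
  writeLines(paste(format(dwi@scheme@bvals, trim = TRUE), collapse = " "),
             bvalPath)
  write.table(t(dwi@scheme@bvecs), bvecPath, row.names = FALSE,
              col.names = FALSE)
  invisible(niftiPath)
}

niftiAffine <- function(img) {
  a <- structure(RNifti::xform(img), class = NULL)
  matrix(as.numeric(a), 4, 4, dimnames = NULL)
}

#' Read a binary mask on a reference grid
#'
#' No silent resampling: the mask must share the reference's grid shape and
#' affine (to 1e-3).
#'
#' @param path NIfTI mask file (nonzero = inside).
#' @param reference a \linkS4class{DWIVolume} defining the grid.
#' @return A \linkS4class{BinaryMask}.
#' @export
readMask <- function(path, reference) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img))
  if (length(dim(data)) != 3L) stop("mask must be 3D: ", path)
  if (!all(dim(data) == dim(reference@data)[1:3]))
    stop("mask grid ", paste(dim(data), collapse = "x"),
         " does not match reference ",
         paste(dim(reference@data)[1:3], collapse = "x"))
  affine <- niftiAffine(img)
  if (max(abs(affine - reference@affine)) > 1e-3)
    stop("mask affine does not match the reference grid (no resampling is performed)")
  new("BinaryMask", data = array(data != 0, dim = dim(data)),
      affine = reference@affine)
}

#' Write a binary mask or scalar map as NIfTI
#' @param x a \linkS4class{BinaryMask}, or a 3D/4D numeric array.
#' @param path output file.
#' @param affine voxel-to-world affine (taken from \code{x} for masks).
#' @export
writeVolume <- function(x, path, affine = NULL) {
  if (is(x, "BinaryMask")) {
    affine <- x@affine
    x <- array(as.numeric(x@data), dim = dim(x@data))
  }
  stopifnot(!is.null(affine))
  img <- RNifti::asNifti(x)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

## ---- TRK ------------------------------------------------------------------
## TrackVis format: 1000-byte header, then per-track int32 point count and
## float32 xyz triplets in "voxmm" coordinates (continuous voxel index
## scaled by voxel size, voxel centers at i + 0.5).  Read normalizes to
## world mm through the header affine; write stores version-2 files with the
## tractogram's reference affine.

readTRK <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- rawToChar(readBin(con, "raw", 5))
  invisible(readBin(con, "raw", 1))
  if (!identical(id, "TRACK")) stop("not a TRK file: ", path)
  dim3 <- readBin(con, "integer", 3, size = 2)
  voxel <- readBin(con, "numeric", 3, size = 4)
  invisible(readBin(con, "numeric", 3, size = 4))           # origin (unused)
  nScalars <- readBin(con, "integer", 1, size = 2)
  invisible(readBin(con, "raw", 200))                        # scalar names
  nProps <- readBin(con, "integer", 1, size = 2)
  invisible(readBin(con, "raw", 200))                        # property names
  vox2ras <- matrix(readBin(con, "numeric", 16, size = 4), 4, 4, byrow = TRUE)
  invisible(readBin(con, "raw", 444))
  invisible(readBin(con, "raw", 4))                          # voxel_order
  invisible(readBin(con, "raw", 4))
  invisible(readBin(con, "numeric", 6, size = 4))
  invisible(readBin(con, "raw", 2))
  invisible(readBin(con, "raw", 6))                          # invert/swap
  nCount <- readBin(con, "integer", 1, size = 4)
  invisible(readBin(con, "integer", 1, size = 4))            # version
  hdrSize <- readBin(con, "integer", 1, size = 4)
  if (hdrSize != 1000L) stop("unexpected TRK header size: ", hdrSize)
  if (all(vox2ras == 0)) {                 # legacy files: assume axis-aligned
    vox2ras <- diag(c(voxel, 1))
  }
  voxel[voxel == 0] <- 1
  streams <- list()
  repeat {
    npts <- readBin(con, "integer", 1, size = 4)
    if (length(npts) == 0L) break
    vals <- readBin(con, "numeric", npts * (3 + nScalars) + nProps, size = 4)
    xyz <- matrix(vals[seq_len(npts * (3 + nScalars))],
                  ncol = 3 + nScalars, byrow = TRUE)[, 1:3, drop = FALSE]
    ## voxmm -> continuous voxel (center-based) -> world
    vox <- sweep(xyz, 2, voxel, "/") - 0.5
    streams[[length(streams) + 1L]] <- applyAffine(vox2ras, vox)
    if (nCount > 0L && length(streams) == nCount) break
  }
  tractogram(streams, affine = vox2ras)
}

writeTRK <- function(tg, path) {
  affine <- tg@affine
  voxel <- sqrt(colSums(affine[1:3, 1:3]^2))
  voxel[voxel == 0] <- 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), raw(1)), con)     # id_string, nul-padded
  writeBin(as.integer(c(1, 1, 1)), con, size = 2)
  writeBin(as.numeric(voxel), con, size = 4)
  writeBin(numeric(3), con, size = 4)              # origin
  writeBin(0L, con, size = 2)                      # n_scalars
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2)                      # n_properties
  writeBin(raw(200), con)
  writeBin(as.numeric(t(affine)), con, size = 4)   # vox_to_ras, row-major
  writeBin(raw(444), con)
  writeBin(c(charToRaw("LPS"), raw(1)), con)       # voxel_order, nul-padded
  writeBin(raw(4), con)
  writeBin(numeric(6), con, size = 4)
  writeBin(raw(2), con)
  writeBin(raw(6), con)
  writeBin(length(tg@streamlines), con, size = 4)
  writeBin(2L, con, size = 4)                      # version
  writeBin(1000L, con, size = 4)
  inv <- solve(affine)
  for (s in tg@streamlines) {
    vox <- applyAffine(inv, s) + 0.5
    xyz <- sweep(vox, 2, voxel, "*")
    writeBin(nrow(s), con, size = 4)
    writeBin(as.numeric(t(xyz)), con, size = 4)
  }
  invisible(path)
}

## ---- TCK ------------------------------------------------------------------
## MRtrix format: text header terminated by END, then Float32LE xyz triplets
## in world mm; NaN triplet separates streamlines, Inf triplet ends the file.

readTCK <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  if (!grepl("^mrtrix tracks", first)) stop("not a TCK file: ", path)
  offset <- NA_real_
  datatype <- "Float32LE"
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0L) stop("unterminated TCK header")
    if (ln == "END") break
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    if (key == "file") offset <- as.numeric(sub("^\\.\\s*", "", val))
    if (key == "datatype") datatype <- val
  }
  if (datatype != "Float32LE")
    stop("unsupported TCK datatype: ", datatype)
  seek(con, where = offset, origin = "start")
  vals <- readBin(con, "numeric", n = file.size(path), size = 4,
                  endian = "little")
  pts <- matrix(vals[seq_len(3 * (length(vals) %/% 3))], ncol = 3,
                byrow = TRUE)
  streams <- list()
  cur <- 1L
  for (i in seq_len(nrow(pts))) {
    if (!all(is.finite(pts[i, ]))) {
      if (i > cur) streams[[length(streams) + 1L]] <- pts[cur:(i - 1L), ,
                                                          drop = FALSE]
      cur <- i + 1L
      if (all(is.infinite(pts[i, ]))) break
    }
  }
  tractogram(streams)
}

writeTCK <- function(tg, path) {
  hdr <- c("mrtrix tracks", "datatype: Float32LE",
           sprintf("count: %d", length(tg@streamlines)))
  ## compute the data offset: header + "file: . NNN\nEND\n"
  repeat {
    guess <- sum(nchar(hdr) + 1L) + nchar("file: . ") + 20L + nchar("END") + 2L
    fileLine <- sprintf("file: . %d", guess)
    lines <- c(hdr, fileLine, "END")
    if (sum(nchar(lines) + 1L) <= guess) break
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  pad <- guess - sum(nchar(lines) + 1L)
  if (pad > 0) writeBin(raw(pad), con)
  for (s in tg@streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4, endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a tractogram (TRK or TCK)
#'
#' Coordinates are returned in world mm regardless of the on-disk
#' convention; TRK voxel-order/offset quirks are normalized at read time.
#'
#' @param path file ending in .trk or .tck.
#' @return A \linkS4class{Tractogram}.
#' @export
readTractogram <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         trk = readTRK(path),
         tck = readTCK(path),
         stop("unknown tractogram extension '.", ext, "' (need .trk or .tck)"))
}

#' Write a tractogram (TRK or TCK)
#'
#' Round-trip write/read preserves coordinates to better than 1e-4 mm
#' relative to float32 precision of the on-disk format.
#'
#' @param tg a \linkS4class{Tractogram}.
#' @param path file ending in .trk or .tck.
#' @export
writeTractogram <- function(tg, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         trk = writeTRK(tg, path),
         tck = writeTCK(tg, path),
         stop("unknown tractogram extension '.", ext, "' (need .trk or .tck)"))
}
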