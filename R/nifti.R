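# Minimal NIfTI-1 I/O (single-file .nii / .nii.gz, little-endian).
# The installed R stack ships no NIfTI package, so the subset needed here —
# 3D/4D volumes, float32/float64/int datatypes, voxel sizes in pixdim and a
# diagonal sform — is implemented directly against the NIfTI-1 header
# layout. Offset lists for 4D CEST volumes live in a JSON sidecar (NIfTI
# has no frequency-offset convention); see writeOffsets().

#' Write a volume as NIfTI-1
#'
#' Writes a 3D or 4D array as a little-endian single-file NIfTI-1 volume
#' (float32 data), with voxel sizes in the header (pixdim and a diagonal
#' sform). \code{.gz} paths are compressed transparently.
#'
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @param vol 3D or 4D numeric array.
#' @param voxelSize voxel dimensions in mm (length 3).
#' @return \code{path}, invisibly.
#' @export
writeNifti <- function(path, vol, voxelSize = c(1, 1, 1)) {
  if (any(voxelSize <= 0)) stop("voxel sizes must be positive")
  d <- dim(vol)
  if (!(length(d) %in% c(3L, 4L))) stop("vol must be 3D or 4D")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wInt <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4,
                               endian = "little")
  wRaw <- function(x, n) {
    r <- raw(n)
    b <- charToRaw(x)
    r[seq_along(b)] <- b
    writeBin(r, con)
  }
  wInt(348, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                         # unused ANALYZE fields
  dimv <- c(length(d), d, rep(1L, 7 - length(d)))
  wInt(dimv, 2)                                  # dim[8]
  wFlt(c(0, 0, 0))                               # intent_p1..p3
  wInt(0, 2)                                     # intent_code
  wInt(16, 2); wInt(32, 2); wInt(0, 2)           # datatype f32, bitpix, slice_start
  pix <- c(1, voxelSize, rep(1, 4))
  wFlt(pix)                                      # pixdim[8]
  wFlt(352)                                      # vox_offset
  wFlt(c(1, 0))                                  # scl_slope, scl_inter
  wInt(0, 2)                                     # slice_end
  writeBin(as.raw(c(0L, 10L)), con)              # slice_code; xyzt = mm|s
  wFlt(c(0, 0, 0, 0))                            # cal_max..toffset
  wInt(c(0, 0), 4)                               # glmax, glmin
  wRaw("cestph volume", 80)                      # descrip
  wRaw("", 24)                                   # aux_file
  wInt(c(0, 1), 2)                               # qform 0, sform 1
  wFlt(rep(0, 6))                                # quaternions
  wFlt(c(voxelSize[1], 0, 0, 0))                 # srow_x
  wFlt(c(0, voxelSize[2], 0, 0))                 # srow_y
  wFlt(c(0, 0, voxelSize[3], 0))                 # srow_z
  wRaw("", 16)                                   # intent_name
  wRaw("n+1", 4)                                 # magic
  writeBin(raw(4), con)                          # extension flag
  v <- as.numeric(vol)
  v[!is.finite(v)] <- NA
  writeBin(v, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads single-file little- or big-endian NIfTI-1 (\code{.nii} /
#' \code{.nii.gz}) with uint8/int16/int32/float32/float64 data, applying
#' scl_slope/scl_inter when set.
#'
#' @param path input path.
#' @return list with \code{data} (array) and \code{voxelSize} (mm).
#' @export
readNifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("malformed NIfTI header in ", path)
  rInt <- function(off, size, n = 1, endian = "little")
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian)
  rFlt <- function(off, n = 1, endian = "little")
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = endian)
  endian <- "little"
  if (rInt(0, 4) != 348L) {
    endian <- "big"
    if (rInt(0, 4, endian = "big") != 348L)
      stop("malformed NIfTI header in ", path, " (sizeof_hdr != 348)")
  }
  dimv <- rInt(40, 2, 8, endian)
  nd <- dimv[1]
  if (nd < 3 || nd > 4) stop("only 3D/4D NIfTI supported: ", path)
  d <- dimv[2:(1 + nd)]
  datatype <- rInt(70, 2, endian = endian)
  pixdim <- rFlt(76, 8, endian)
  voxOffset <- rFlt(108, 1, endian)
  slope <- rFlt(112, 1, endian); inter <- rFlt(116, 1, endian)
  if (any(pixdim[2:4] <= 0)) stop("malformed header (non-positive voxel size) in ", path)
  n <- prod(d)
  # skip to the data (sequential for gz support)
  toSkip <- as.integer(voxOffset) - 348L
  if (toSkip > 0) readBin(con, "raw", toSkip)
  data <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "4" = as.numeric(readBin(con, "integer", n, size = 2, endian = endian)),
    "8" = as.numeric(readBin(con, "integer", n, size = 4, endian = endian)),
    "16" = readBin(con, "double", n, size = 4, endian = endian),
    "64" = readBin(con, "double", n, size = 8, endian = endian),
    stop("unsupported NIfTI datatype ", datatype, " in ", path))
  if (length(data) < n) stop("truncated NIfTI data in ", path)
  if (slope != 0 && !(slope == 1 && inter == 0)) data <- data * slope + inter
  list(data = array(data, d), voxelSize = pixdim[2:4])
}

#' Offset sidecar files
#'
#' The ppm offset list of a 4D CEST volume is stored alongside the NIfTI in
#' a JSON sidecar (offset order = 4D volume order, water = 0 ppm).
#'
#' @param offsets numeric ppm vector.
#' @param path sidecar path (conventionally \code{<volume>.offsets.json}).
#' @return \code{readOffsets} returns the ppm vector.
#' @name offsetSidecar
NULL

#' @rdname offsetSidecar
#' @export
writeOffsets <- function(offsets, path) {
  jsonlite::write_json(list(unit = "ppm", offsets = offsets), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname offsetSidecar
#' @export
readOffsets <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)$offsets
}

#' Write a rendered dataset to a directory
#'
#' Emits every grid of an \linkS4class{AcquiredDataset} as NIfTI with
#' correct voxel-size headers, the offset sidecar, and a JSON manifest
#' (paths, seed, configuration hash).
#'
#' @param dataset an \linkS4class{AcquiredDataset}.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- dataset@voxelSize
  p <- function(f) file.path(dir, f)
  writeNifti(p("cest.nii.gz"), dataset@cest4d, vs)
  writeNifti(p("m0.nii.gz"), dataset@m0, vs)
  writeNifti(p("db0.nii.gz"), dataset@db0, vs)
  writeNifti(p("qt1.nii.gz"), dataset@qt1, vs)
  writeNifti(p("mask.nii.gz"), array(as.numeric(dataset@mask),
                                     dim(dataset@mask)), vs)
  writeNifti(p("truth_ph.nii.gz"), dataset@truthPh, vs)
  ph31 <- dataset@ph31p
  writeNifti(p("ph31p.nii.gz"), ph31$ph, ph31$voxelSize)
  writeOffsets(dataset@schedule@offsets, p("cest.offsets.json"))
  writeSchedule(dataset@schedule, p("schedule.json"))
  manifest <- list(
    files = list(cest = "cest.nii.gz", m0 = "m0.nii.gz", db0 = "db0.nii.gz",
                 qt1 = "qt1.nii.gz", mask = "mask.nii.gz",
                 truth_ph = "truth_ph.nii.gz", ph31p = "ph31p.nii.gz",
                 offsets = "cest.offsets.json", schedule = "schedule.json"),
    seed = dataset@seed,
    voxelSize = vs,
    ph31pVoxelSize = ph31$voxelSize,
    scheduleHash = .scheduleHash(dataset@schedule))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(p("manifest.json"))
}
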