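# --- shared point-spread-function downsampling machinery ---
#
# Both the phantom's 31P rendering path and the evaluation module's
# downsampler use the same separable weighting:
#   "box"      — volume-weighted mean over the coarse voxel footprint
#   "gaussian" — Gaussian PSF with FWHM equal to the coarse pitch per
#                dimension, emulating the spatial leakage of zero-filled
#                chemical shift imaging.
# Weights are renormalized over in-mask fine voxels; coarse voxels with an
# in-mask support fraction below `minSupport` are dropped (NA, mask FALSE).

# 1D weight matrix (nCoarse x nFine) for one axis
.psfWeights1d <- function(nFine, fineV, nCoarse, coarseV, mode) {
  fc <- .axisCenters(nFine, fineV)
  W <- matrix(0, nCoarse, nFine)
  for (j in seq_len(nCoarse)) {
    lo <- (j - 1) * coarseV; hi <- j * coarseV
    if (mode == "box") {
      # overlap length of each fine cell with the coarse cell
      flo <- fc - fineV / 2; fhi <- fc + fineV / 2
      W[j, ] <- pmax(0, pmin(hi, fhi) - pmax(lo, flo)) / fineV
    } else {
      cc <- (lo + hi) / 2
      sd <- coarseV / (2 * sqrt(2 * log(2)))  # FWHM = coarse pitch
      W[j, ] <- exp(-(fc - cc)^2 / (2 * sd^2))
    }
  }
  W
}

# contract a 3D array with per-axis weight matrices (separable kernel)
.contract3 <- function(vol, Wx, Wy, Wz) {
  d <- dim(vol)
  v <- Wx %*% matrix(vol, d[1], d[2] * d[3])            # cx x (y z)
  v <- array(v, c(nrow(Wx), d[2], d[3]))
  v <- aperm(v, c(2, 1, 3))
  v <- Wy %*% matrix(v, d[2], nrow(Wx) * d[3])          # cy x (cx z)
  v <- array(v, c(nrow(Wy), nrow(Wx), d[3]))
  v <- aperm(v, c(3, 2, 1))
  v <- Wz %*% matrix(v, d[3], nrow(Wx) * nrow(Wy))      # cz x (cx cy)
  aperm(array(v, c(nrow(Wz), nrow(Wx), nrow(Wy))), c(2, 3, 1))
}

# core PSF downsample: returns list(values, mask, support)
.psfDownsample <- function(vol, mask, fineVoxel, coarseVoxel,
                           mode = c("box", "gaussian"), minSupport = 0.5) {
  mode <- match.arg(mode)
  d <- dim(vol)
  stopifnot(length(d) == 3L, identical(d, dim(mask)))
  if (any(coarseVoxel < fineVoxel))
    stop("coarse voxel must be >= fine voxel in every dimension")
  nC <- as.integer(ceiling(d * fineVoxel / coarseVoxel))
  Wx <- .psfWeights1d(d[1], fineVoxel[1], nC[1], coarseVoxel[1], mode)
  Wy <- .psfWeights1d(d[2], fineVoxel[2], nC[2], coarseVoxel[2], mode)
  Wz <- .psfWeights1d(d[3], fineVoxel[3], nC[3], coarseVoxel[3], mode)
  m <- array(as.numeric(mask), d)
  v <- vol; v[!mask] <- 0
  num <- .contract3(v, Wx, Wy, Wz)
  den <- .contract3(m, Wx, Wy, Wz)
  tot <- .contract3(array(1, d), Wx, Wy, Wz)
  support <- ifelse(tot > 0, den / tot, 0)
  out <- ifelse(den > 0, num / den, NA_real_)
  keep <- support >= minSupport
  out[!keep] <- NA_real_
  list(values = out, mask = keep, support = support,
       voxelSize = as.numeric(coarseVoxel))
}

#' Downsample a high-resolution map onto a coarse target grid
#'
#' PSF-aware downsampling onto the geometry of a low-resolution reference
#' (e.g. the 31P-MRS grid): \code{"box"} is a volume-weighted mean over each
#' coarse voxel footprint; \code{"gaussian"} uses a Gaussian PSF with FWHM
#' equal to the coarse pitch, emulating zero-filled-CSI leakage. Weights are
#' renormalized over in-mask fine voxels and coarse voxels with less than
#' \code{minSupport} in-mask weight are dropped. This is the same machinery
#' the phantom's own 31P rendering uses, so simulated targets and
#' downsampled predictions live on identical grids.
#'
#' @param mapHi 3D array at fine resolution.
#' @param hiVoxel,loVoxel voxel pitches in mm (length-3).
#' @param psfMode \code{"box"} or \code{"gaussian"}.
#' @param mask logical 3D array at fine resolution (default: all finite
#'   voxels of \code{mapHi}).
#' @param minSupport minimum in-mask weight fraction for a coarse voxel.
#' @return list with \code{values} (coarse 3D array, NA where dropped),
#'   \code{mask}, \code{support} and \code{voxelSize}.
#' @export
downsampleToTarget <- function(mapHi, hiVoxel, loVoxel,
                               psfMode = c("box", "gaussian"),
                               mask = NULL, minSupport = 0.5) {
  if (is.null(mask)) mask <- is.finite(mapHi)
  if (!identical(dim(mapHi), dim(mask)))
    stop("map and mask are on disjoint grids")
  .psfDownsample(mapHi, mask, rep(hiVoxel, length.out = 3),
                 rep(loVoxel, length.out = 3), match.arg(psfMode),
                 minSupport)
}

#' Nearest-neighbour upsampling of a coarse map onto a fine grid
#'
#' Assigns to every fine voxel the value of the coarse voxel whose footprint
#' contains its center (both grids anchored at the same corner). Used to
#' paste low-resolution 31P pH targets onto the CEST grid for voxel-wise
#' training, mirroring the reslicing of measured 31P maps.
#'
#' @param mapLo coarse 3D array.
#' @param loVoxel coarse pitch, mm.
#' @param hiDim fine grid dimensions.
#' @param hiVoxel fine pitch, mm.
#' @return 3D array at fine resolution (NA where the coarse value is NA or
#'   the fine voxel falls outside the coarse grid).
#' @export
upsampleNearest <- function(mapLo, loVoxel, hiDim, hiVoxel) {
  loVoxel <- rep(loVoxel, length.out = 3)
  hiVoxel <- rep(hiVoxel, length.out = 3)
  dLo <- dim(mapLo)
  idx <- lapply(1:3, function(k) {
    i <- ceiling(.axisCenters(hiDim[k], hiVoxel[k]) / loVoxel[k])
    i[i < 1 | i > dLo[k]] <- NA_integer_
    i
  })
  out <- array(NA_real_, hiDim)
  ii <- array(idx[[1]], hiDim)
  jj <- array(rep(idx[[2]], each = hiDim[1]), hiDim)
  kk <- array(rep(idx[[3]], each = hiDim[1] * hiDim[2]), hiDim)
  ok <- !is.na(ii) & !is.na(jj) & !is.na(kk)
  out[ok] <- mapLo[cbind(ii[ok], jj[ok], kk[ok])]
  out
}
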