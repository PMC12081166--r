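#' Normalize raw CEST data by the unsaturated reference
#'
#' Z = raw / M0 per voxel and offset. Voxels with an M0 at or below
#' \code{epsilon} times the M0 maximum are masked out rather than divided.
#' The offset axis is canonicalized to strictly increasing order (the data
#' planes are re-ordered accordingly).
#'
#' @param raw4d raw CEST signal, 4D array (x, y, z, offset).
#' @param m0 unsaturated reference, 3D array.
#' @param offsets saturation offsets, ppm (length = 4th dim of raw4d).
#' @param voxelSize mm triple.
#' @param mask optional logical 3D array restricting the output mask.
#' @param epsilon relative M0 floor.
#' @return A \linkS4class{ZSpectrumVolume}.
#' @export
normalizeZ <- function(raw4d, m0, offsets, voxelSize = c(3, 3, 4),
                       mask = NULL, epsilon = 1e-9) {
  d <- dim(raw4d)
  if (length(d) != 4L || !identical(d[1:3], dim(m0)))
    stop("raw4d must be 4D and match the m0 grid")
  if (d[4] != length(offsets))
    stop("offset count must match the 4th dimension of raw4d")
  ord <- order(offsets)
  offsets <- offsets[ord]
  if (anyDuplicated(offsets)) stop("offsets must be unique")
  raw4d <- raw4d[, , , ord, drop = FALSE]
  valid <- m0 > epsilon * max(m0)
  if (!is.null(mask)) valid <- valid & as.logical(mask)
  z <- array(0, d)
  denom <- ifelse(valid, m0, NA_real_)
  n3 <- prod(d[1:3])
  for (k in seq_len(d[4])) {
    zk <- array(raw4d[(k - 1L) * n3 + seq_len(n3)], d[1:3]) / denom
    zk[!valid] <- 0
    z[(k - 1L) * n3 + seq_len(n3)] <- zk
  }
  new("ZSpectrumVolume", offsets = offsets, z = z,
      voxelSize = as.numeric(voxelSize), mask = valid,
      extrapolated = array(FALSE, d[1:3]))
}

#' B0-correct a Z-spectrum volume
#'
#' WASSR-style re-centering: a voxel whose water resonates \code{db0} ppm
#' off-center sees the nominal offset \code{x} probe the tissue at
#' \code{x - db0}, so its measured samples are placed at
#' \code{offsets - db0} and re-interpolated onto the nominal offsets with a
#' monotone cubic interpolant. Edge offsets that would extrapolate are
#' filled with the nearest valid value and the voxel is flagged in the
#' \code{extrapolated} slot. Voxels with a non-finite delta-B0 are masked.
#'
#' @param zvol a \linkS4class{ZSpectrumVolume}.
#' @param db0Map delta-B0 map in ppm (3D array), positive where the water
#'   minimum appears at positive nominal offsets.
#' @return A corrected \linkS4class{ZSpectrumVolume}.
#' @export
b0Correct <- function(zvol, db0Map) {
  offs <- zvol@offsets
  halfRange <- diff(range(offs)) / 2
  d <- dim(zvol@z)
  if (!identical(dim(db0Map), d[1:3]))
    stop("db0 map must match the spectral grid")
  mask <- zvol@mask & is.finite(db0Map)
  bad <- abs(db0Map) >= halfRange
  bad[is.na(bad)] <- TRUE
  mask <- mask & !bad
  idx <- which(mask)
  z <- zvol@z
  n3 <- prod(d[1:3])
  K <- d[4]
  extrap <- zvol@extrapolated
  zm <- matrix(0, length(idx), K)
  for (k in seq_len(K)) zm[, k] <- z[idx + (k - 1L) * n3]
  db0 <- db0Map[idx]
  for (v in seq_along(idx)) {
    b <- db0[v]
    if (b == 0) next
    xs <- offs - b
    sf <- stats::splinefun(xs, zm[v, ], method = "monoH.FC")
    lo <- offs < xs[1]; hi <- offs > xs[K]
    zi <- sf(pmin(pmax(offs, xs[1]), xs[K]))
    zi[lo] <- zm[v, 1]; zi[hi] <- zm[v, K]
    if (any(lo | hi)) extrap[idx[v]] <- TRUE
    zm[v, ] <- zi
  }
  for (k in seq_len(K)) z[idx + (k - 1L) * n3] <- zm[, k]
  off3 <- which(!mask)
  for (k in seq_len(K)) z[off3 + (k - 1L) * n3] <- 0
  new("ZSpectrumVolume", offsets = offs, z = z, voxelSize = zvol@voxelSize,
      mask = mask, extrapolated = extrap)
}

# Z values at a given ppm, linear interpolation between neighbouring offsets
.zAt <- function(zvol, ppm) {
  offs <- zvol@offsets
  if (ppm < min(offs) || ppm > max(offs))
    stop("delta_omega ", ppm, " ppm outside the sampled offset range")
  d <- dim(zvol@z)
  n3 <- prod(d[1:3])
  plane <- function(k) array(zvol@z[(k - 1L) * n3 + seq_len(n3)], d[1:3])
  k <- findInterval(ppm, offs)
  if (offs[k] == ppm) return(plane(k))
  w <- (ppm - offs[k]) / (offs[k + 1] - offs[k])
  (1 - w) * plane(k) + w * plane(k + 1)
}

#' Magnetization transfer ratio asymmetry
#'
#' \deqn{MTR_{asym}(\Delta\omega) = Z(-\Delta\omega) - Z(+\Delta\omega)}
#' with linear interpolation when the offsets are not sampled exactly.
#'
#' @param zvol a \linkS4class{ZSpectrumVolume}.
#' @param deltaOmega evaluation offset, ppm (within the sampled range on
#'   both signs).
#' @return A \linkS4class{MetricMap} named \code{"MTR_asym"}.
#' @export
mtrAsym <- function(zvol, deltaOmega = 3.5) {
  v <- .zAt(zvol, -deltaOmega) - .zAt(zvol, deltaOmega)
  v[!zvol@mask] <- 0
  new("MetricMap", name = "MTR_asym", deltaOmega = deltaOmega, values = v,
      mask = zvol@mask, voxelSize = zvol@voxelSize)
}

#' APT-weighted MTRasym block
#'
#' [mtrAsym()] evaluated on the amide band grid 3.0, 3.1, ..., 4.0 ppm
#' (11 values per voxel), the APT-weighted feature block of the predictive
#' model.
#'
#' @param zvol a \linkS4class{ZSpectrumVolume}.
#' @param start,stop,step band definition, ppm.
#' @return A \linkS4class{MetricMap} with a 4D \code{values} array whose
#'   last axis runs over the band offsets.
#' @export
mtrAsymBlock <- function(zvol, start = 3.0, stop = 4.0, step = 0.1) {
  dw <- seq(start, stop, by = step)
  d <- dim(zvol@z)[1:3]
  n3 <- prod(d)
  v <- array(0, c(d, length(dw)))
  for (i in seq_along(dw))
    v[(i - 1L) * n3 + seq_len(n3)] <- mtrAsym(zvol, dw[i])@values
  new("MetricMap", name = "MTR_asym", deltaOmega = dw, values = v,
      mask = zvol@mask, voxelSize = zvol@voxelSize)
}

#' Spillover-corrected magnetization transfer ratio (MTRrex)
#'
#' Inverse-Z difference metric with the opposite-side Z value as reference:
#' \deqn{MTR_{rex}(\Delta\omega) = \frac{1}{Z(+\Delta\omega)} -
#'       \frac{1}{Z(-\Delta\omega)}}
#' Voxels where either Z falls below \code{zFloor} (spillover-dominated,
#' the inverse terms blow up) are masked and reported.
#'
#' @param zvol a \linkS4class{ZSpectrumVolume}.
#' @param deltaOmega evaluation offset, ppm.
#' @param zFloor minimum admissible Z.
#' @return A \linkS4class{MetricMap} named \code{"MTR_rex"}; floored voxels
#'   are reported via a message, not silently dropped.
#' @export
mtrRex <- function(zvol, deltaOmega = 3.5, zFloor = 0.05) {
  zp <- .zAt(zvol, deltaOmega)
  zn <- .zAt(zvol, -deltaOmega)
  ok <- zvol@mask & zp > zFloor & zn > zFloor
  nf <- sum(zvol@mask & !ok)
  if (nf > 0) message(nf, " voxel(s) below the Z floor were masked")
  v <- array(0, dim(zp))
  v[ok] <- 1 / zp[ok] - 1 / zn[ok]
  new("MetricMap", name = "MTR_rex", deltaOmega = deltaOmega, values = v,
      mask = ok, voxelSize = zvol@voxelSize)
}

#' Apparent exchange-dependent relaxation (AREX)
#'
#' T1-corrected MTRrex: \deqn{AREX = MTR_{rex} \cdot R_1 = MTR_{rex}/T_1}
#' in 1/s. Voxels with non-positive T1 are masked.
#'
#' @param mtrRexMap a \code{"MTR_rex"} \linkS4class{MetricMap}.
#' @param qt1 quantitative T1 map, s (3D array).
#' @return A \linkS4class{MetricMap} named \code{"AREX"}.
#' @export
arex <- function(mtrRexMap, qt1) {
  stopifnot(is(mtrRexMap, "MetricMap"), mtrRexMap@name == "MTR_rex")
  if (!identical(dim(qt1), dim(mtrRexMap@values)))
    stop("qt1 grid does not match the metric map")
  ok <- mtrRexMap@mask & is.finite(qt1) & qt1 > 0
  v <- array(0, dim(qt1))
  v[ok] <- mtrRexMap@values[ok] / qt1[ok]
  new("MetricMap", name = "AREX", deltaOmega = mtrRexMap@deltaOmega,
      values = v, mask = ok, voxelSize = mtrRexMap@voxelSize)
}
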