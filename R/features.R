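#' Assemble per-voxel feature vectors
#'
#' One row per masked voxel, in flattened (column-major) voxel index order:
#' the B0-corrected Z-spectrum block (one value per schedule offset), the
#' 11-point APT-weighted MTRasym block (3.0 to 4.0 ppm) and the
#' quantitative T1 value. Voxels with a non-finite value in any channel are
#' dropped and counted.
#'
#' @param zvol a \linkS4class{ZSpectrumVolume} (B0-corrected upstream).
#' @param asymBlock the \linkS4class{MetricMap} from [mtrAsymBlock()].
#' @param qt1 quantitative T1 map, s (3D array).
#' @param mask logical 3D array (eroded upstream).
#' @return list with \code{x} (numeric matrix, voxels x features),
#'   \code{voxels} (linear voxel indices of the rows), \code{dropped}
#'   (count of NaN-dropped voxels) and \code{featureNames}.
#' @export
assembleFeatures <- function(zvol, asymBlock, qt1, mask) {
  d <- dim(zvol@z)
  stopifnot(identical(d[1:3], dim(mask)), identical(d[1:3], dim(qt1)))
  K <- d[4]
  nA <- dim(asymBlock@values)[4]
  idx <- which(mask & zvol@mask & asymBlock@mask)
  n3 <- prod(d[1:3])
  x <- matrix(NA_real_, length(idx), K + nA + 1L)
  for (k in seq_len(K)) x[, k] <- zvol@z[idx + (k - 1L) * n3]
  for (k in seq_len(nA)) x[, K + k] <- asymBlock@values[idx + (k - 1L) * n3]
  x[, K + nA + 1L] <- qt1[idx]
  ok <- rowSums(!is.finite(x)) == 0L
  list(x = x[ok, , drop = FALSE], voxels = idx[ok],
       dropped = sum(!ok),
       featureNames = c(paste0("Z_", format(zvol@offsets, trim = TRUE)),
                        paste0("MTRasym_",
                               format(asymBlock@deltaOmega, trim = TRUE)),
                        "qT1"))
}

#' Standardize a feature table
#'
#' Column-wise (x - mean) / sd. With \code{stats} supplied the given
#' statistics are applied (never recomputed) — in the training pipeline the
#' statistics are computed on the training split only and then frozen.
#' Zero-variance columns are pinned to sd = 1 with a warning.
#'
#' @param x numeric matrix (rows = voxels) or vector (targets).
#' @param stats optional list with \code{mean} and \code{sd}.
#' @return list with the standardized \code{x} and the \code{stats} used.
#' @export
standardizeFeatures <- function(x, stats = NULL) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  if (is.null(stats)) {
    if (nrow(xm) < 2) stop("need >= 2 rows to compute statistics")
    mu <- colMeans(xm)
    sdv <- apply(xm, 2, stats::sd)
    if (any(sdv == 0)) {
      warning(sum(sdv == 0), " zero-variance dimension(s) pinned to sd = 1")
      sdv[sdv == 0] <- 1
    }
    stats <- list(mean = mu, sd = sdv)
  }
  out <- sweep(sweep(xm, 2, stats$mean, "-"), 2, stats$sd, "/")
  if (vec) out <- drop(out)
  list(x = out, stats = stats)
}

# invert standardization
.destandardize <- function(x, stats) x * stats$sd + stats$mean
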