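#' Root-mean-square error over a mask
#'
#' @param a,b numeric arrays of equal shape.
#' @param mask logical array (default: where both are finite).
#' @return sqrt(mean((a - b)^2)) over the masked voxels.
#' @export
rmse <- function(a, b, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(a) & is.finite(b)
  if (!any(mask)) stop("empty mask")
  sqrt(mean((a[mask] - b[mask])^2))
}

# separable Gaussian filtering of a 2D slice with mask renormalization:
# returns the locally weighted mean of `img` over in-mask pixels
.gaussFilter2dMasked <- function(img, mask, sigma = 1.5) {
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  conv1 <- function(m, along) {
    if (along == 2) m <- t(m)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
    }
    if (along == 2) t(out) else out
  }
  w <- matrix(as.numeric(mask), nrow(img), ncol(img))
  iv <- img * w
  num <- conv1(conv1(iv, 1), 2)
  den <- conv1(conv1(w, 1), 2)
  ifelse(den > 0, num / den, 0)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with a Gaussian window (sd 1.5 voxels) and the standard
#' stabilization constants \eqn{C_1 = (K_1 L)^2}, \eqn{C_2 = (K_2 L)^2}
#' with \eqn{K_1 = 0.01}, \eqn{K_2 = 0.03} and dynamic range \eqn{L}
#' (supplied, or computed from \code{b}, the reference). Local windows are
#' renormalized over in-mask voxels so masked medical images do not leak
#' background into the statistics. Computed per axial slice and averaged
#' over in-mask voxels (\code{mode3d = TRUE} uses a 3D window instead).
#'
#' @param a,b 3D arrays (test, reference).
#' @param mask logical 3D array.
#' @param dynamicRange value range L; default \code{diff(range(b[mask]))}.
#' @param sigma Gaussian window sd in voxels.
#' @param K1,K2 stabilization constants.
#' @param mode3d window in 3D instead of per-slice.
#' @return Scalar mean SSIM in \[-1, 1\].
#' @export
ssim <- function(a, b, mask = NULL, dynamicRange = NULL, sigma = 1.5,
                 K1 = 0.01, K2 = 0.03, mode3d = FALSE) {
  stopifnot(identical(dim(a), dim(b)))
  if (is.null(mask)) mask <- is.finite(a) & is.finite(b)
  if (!any(mask)) stop("empty mask")
  if (is.null(dynamicRange)) dynamicRange <- diff(range(b[mask]))
  C1 <- (K1 * dynamicRange)^2
  C2 <- (K2 * dynamicRange)^2
  ssimSlice <- function(as, bs, ms) {
    as[!ms] <- 0; bs[!ms] <- 0
    mua <- .gaussFilter2dMasked(as, ms, sigma)
    mub <- .gaussFilter2dMasked(bs, ms, sigma)
    saa <- .gaussFilter2dMasked(as * as, ms, sigma) - mua^2
    sbb <- .gaussFilter2dMasked(bs * bs, ms, sigma) - mub^2
    sab <- .gaussFilter2dMasked(as * bs, ms, sigma) - mua * mub
    s <- ((2 * mua * mub + C1) * (2 * sab + C2)) /
      ((mua^2 + mub^2 + C1) * (saa + sbb + C2))
    s[ms]
  }
  if (mode3d) {
    # treat the volume as one "slice" stack with a 3D separable window
    vals <- .ssim3d(a, b, mask, C1, C2, sigma)
  } else {
    d <- dim(a)
    vals <- unlist(lapply(seq_len(d[3]), function(k) {
      ms <- matrix(mask[, , k], d[1], d[2])
      if (!any(ms)) return(numeric())
      ssimSlice(matrix(a[, , k], d[1], d[2]),
                matrix(b[, , k], d[1], d[2]), ms)
    }))
  }
  mean(vals)
}

.ssim3d <- function(a, b, mask, C1, C2, sigma) {
  w <- array(as.numeric(mask), dim(mask))
  f <- function(v) {
    num <- .gaussSmooth3d(v * w, sigma)
    num
  }
  den <- .gaussSmooth3d(w, sigma)
  g <- function(v) ifelse(den > 0, f(v) / den, 0)
  av <- a; av[!mask] <- 0; bv <- b; bv[!mask] <- 0
  mua <- g(av); mub <- g(bv)
  saa <- g(av * av) - mua^2; sbb <- g(bv * bv) - mub^2
  sab <- g(av * bv) - mua * mub
  s <- ((2 * mua * mub + C1) * (2 * sab + C2)) /
    ((mua^2 + mub^2 + C1) * (saa + sbb + C2))
  s[mask]
}

#' Pearson correlation and coefficient of determination
#'
#' Standard Pearson r over the masked voxels; R2 is reported as the squared
#' Pearson r of the scatter (the convention matching paired r/R2
#' reporting), not as 1 - SSres/SStot against the identity line.
#'
#' @param a,b numeric arrays of equal shape.
#' @param mask logical array (default: where both are finite).
#' @return list with \code{r} and \code{r2}.
#' @export
mapCorrelation <- function(a, b, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(a) & is.finite(b)
  x <- a[mask]; y <- b[mask]
  if (length(x) < 3) stop("need >= 3 masked voxels")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  r <- stats::cor(x, y)
  list(r = r, r2 = r^2)
}

#' Bland-Altman analysis
#'
#' Differences d = a - b over the mask: mean difference, sd (n - 1
#' denominator) and the 95% limits of agreement mean +/- 1.96 sd. Per-voxel
#' (mean, difference) pairs are returned for plotting.
#'
#' @param a,b numeric arrays of equal shape.
#' @param mask logical array (default: where both are finite).
#' @return list with \code{meanDiff}, \code{sd}, \code{loaLow},
#'   \code{loaHigh}, \code{n} and a data.frame \code{points} of
#'   (avg, diff) pairs.
#' @export
blandAltman <- function(a, b, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(a) & is.finite(b)
  x <- a[mask]; y <- b[mask]
  if (length(x) < 2) stop("need >= 2 masked voxels")
  d <- x - y
  m <- mean(d)
  s <- if (length(d) > 1) stats::sd(d) else 0
  list(meanDiff = m, sd = s, loaLow = m - 1.96 * s, loaHigh = m + 1.96 * s,
       n = length(d), points = data.frame(avg = (x + y) / 2, diff = d))
}

#' Full evaluation report
#'
#' RMSE, SSIM, Pearson/R2 and Bland-Altman statistics of a predicted map
#' against a reference on a common grid.
#'
#' @param pred,truth 3D arrays on the same grid.
#' @param mask logical array (default: both finite).
#' @param voxelSize mm triple (metadata only).
#' @return list (report) with the statistics and \code{nVoxels}.
#' @export
evalReport <- function(pred, truth, mask = NULL, voxelSize = c(3, 3, 4)) {
  if (is.null(mask)) mask <- is.finite(pred) & is.finite(truth)
  co <- mapCorrelation(pred, truth, mask)
  ba <- blandAltman(pred, truth, mask)
  list(rmse = rmse(pred, truth, mask),
       ssim = ssim(pred, truth, mask),
       pearsonR = co$r, r2 = co$r2,
       baMeanDiff = ba$meanDiff, baSd = ba$sd,
       baLoaLow = ba$loaLow, baLoaHigh = ba$loaHigh,
       nVoxels = sum(mask), voxelSize = voxelSize)
}

#' Metric-ladder correlation table
#'
#' Ranks the predicted pH map and conventional CEST metric maps by their
#' correlation with the low-resolution truth: every map is PSF-downsampled
#' to the truth grid, z-score normalized over the shared coarse mask and
#' correlated with the truth. Because each map is z-normalized, the ladder
#' is invariant to affine rescaling of any input.
#'
#' @param predMap 3D array of predicted pH at fine resolution.
#' @param metricMaps named list of further 3D arrays (e.g. MTRasym,
#'   MTRrex, AREX, qT1) at fine resolution.
#' @param truthLo coarse truth values (3D array, NA outside its mask).
#' @param hiVoxel,loVoxel fine and coarse voxel sizes, mm.
#' @param mask fine-resolution mask.
#' @param psfMode PSF mode for the downsampling.
#' @return data.frame (metric, r, r2) sorted by decreasing r.
#' @export
metricLadder <- function(predMap, metricMaps, truthLo, hiVoxel, loVoxel,
                         mask, psfMode = c("gaussian", "box")) {
  psfMode <- match.arg(psfMode)
  maps <- c(list(prediction = predMap), metricMaps)
  res <- lapply(names(maps), function(nm) {
    ds <- downsampleToTarget(maps[[nm]], hiVoxel, loVoxel, psfMode,
                             mask = mask)
    common <- ds$mask & is.finite(truthLo) & is.finite(ds$values)
    v <- ds$values[common]
    tr <- truthLo[common]
    v <- (v - mean(v)) / stats::sd(v)
    tz <- (tr - mean(tr)) / stats::sd(tr)
    r <- stats::cor(v, tz)
    data.frame(metric = nm, r = r, r2 = r^2, nVoxels = sum(common))
  })
  out <- do.call(rbind, res)
  out[order(-out$r), , drop = FALSE]
}
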