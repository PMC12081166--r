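# --- small volume utilities shared across modules ---

#' Morphological erosion of a binary mask
#'
#' Erodes a 3D binary mask with a 6-connected (face-neighbour) structuring
#' element, repeated \code{iterations} times. Voxels on the array boundary
#' are treated as adjacent to background.
#'
#' @param mask logical (or 0/1) 3D array.
#' @param iterations number of erosion passes (0 = identity).
#' @return Logical 3D array.
#' @examples
#' m <- array(TRUE, c(5, 5, 5))
#' sum(erodeMask(m, 1))  # 27: the interior 3x3x3 block survives
#' @export
erodeMask <- function(mask, iterations = 1) {
  stopifnot(length(dim(mask)) == 3L, iterations >= 0)
  m <- array(as.logical(mask), dim(mask))
  d <- dim(m)
  for (it in seq_len(iterations)) {
    if (!any(m)) break
    out <- m
    # face neighbours; out-of-range neighbours count as background
    shift <- function(a, dm, by) {
      r <- array(FALSE, d)
      idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      src <- idx; dst <- idx
      n <- d[dm]
      if (by > 0) { dst[[dm]] <- 2:n; src[[dm]] <- 1:(n - 1) }
      else        { dst[[dm]] <- 1:(n - 1); src[[dm]] <- 2:n }
      r[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
      r
    }
    for (dm in 1:3) {
      out <- out & shift(m, dm, 1) & shift(m, dm, -1)
    }
    m <- out
  }
  m
}

# separable Gaussian smoothing of a 3D array (sigma in voxels, per dim),
# with edge-renormalized kernels so constants are preserved.
.gaussSmooth3d <- function(vol, sigma) {
  d <- dim(vol)
  sigma <- rep(sigma, length.out = 3)
  smooth1 <- function(mat, s) {
    # smooth along rows of a (n x m) matrix
    n <- nrow(mat)
    if (s <= 0) return(mat)
    r <- max(1L, ceiling(3 * s))
    x <- (-r):r
    k <- exp(-x^2 / (2 * s^2))
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- i + x
      ok <- j >= 1 & j <= n
      W[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    W %*% mat
  }
  v <- smooth1(matrix(vol, d[1], d[2] * d[3]), sigma[1])
  vol <- array(v, d)
  vol <- aperm(vol, c(2, 1, 3))
  v <- smooth1(matrix(vol, d[2], d[1] * d[3]), sigma[2])
  vol <- aperm(array(v, d[c(2, 1, 3)]), c(2, 1, 3))
  vol <- aperm(vol, c(3, 2, 1))
  v <- smooth1(matrix(vol, d[3], d[2] * d[1]), sigma[3])
  aperm(array(v, d[c(3, 2, 1)]), c(3, 2, 1))
}

# Gaussian random field: white noise smoothed and rescaled to unit sd
# (over the whole grid). Deterministic under the caller's RNG state.
.grf <- function(d, smoothVox = 2) {
  g <- array(stats::rnorm(prod(d)), d)
  g <- .gaussSmooth3d(g, smoothVox)
  g / stats::sd(g)
}

# voxel center coordinates (mm) along one axis for n voxels of pitch v
.axisCenters <- function(n, v) (seq_len(n) - 0.5) * v
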