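#' Phantom geometry configuration
#'
#' Defaults describe an adult-head-sized ellipsoidal brain on the CEST
#' acquisition grid (3 x 3 x 4 mm voxels): a GM shell around WM, two small
#' CSF ventricles, and one spheroidal tumor (rim + necrotic core) placed in
#' one hemisphere. Per-class pH receives smooth within-class variation from
#' a Gaussian random field; the delta-B0 field is a smooth low-order
#' polynomial.
#'
#' @param dim grid dimensions (voxels).
#' @param voxelSize voxel pitch in mm.
#' @param brainSemiAxes brain ellipsoid semi-axes in mm.
#' @param gmThickness cortical shell thickness as a fraction of the
#'   normalized ellipsoid radius.
#' @param ventricleSemiAxes,ventricleOffset CSF ventricle ellipsoids (mm);
#'   two mirrored ventricles at \code{+/- ventricleOffset}.
#' @param tumorCenter tumor center offset from brain center, mm.
#' @param tumorRadius outer tumor radius, mm (0 disables the tumor:
#'   a healthy phantom).
#' @param coreRadius necrotic core radius, mm.
#' @param phByClass named per-class mean pH.
#' @param phSd standard deviation of the within-class pH field (pH units).
#' @param phSmoothVox correlation scale of the pH field (voxels).
#' @param db0Amplitude maximum |delta-B0| inside the brain, ppm.
#' @return A geometry configuration list for [buildPhantom()].
#' @export
phantomGeometry <- function(dim = c(64, 64, 20),
                            voxelSize = c(3, 3, 4),
                            brainSemiAxes = c(84, 90, 36),
                            gmThickness = 0.18,
                            ventricleSemiAxes = c(18, 27, 9),
                            ventricleOffset = c(15, 6, 0),
                            tumorCenter = c(42, 15, 2),
                            tumorRadius = 19,
                            coreRadius = 11,
                            phByClass = c(WM = 7.00, GM = 7.03, CSF = 7.00,
                                          tumor_rim = 7.15,
                                          necrotic_core = 7.25),
                            phSd = 0.02,
                            phSmoothVox = 2,
                            db0Amplitude = 0.3) {
  as.list(environment())
}

#' Build a digital brain-tumor phantom
#'
#' Deterministic for a fixed seed. Assigns tissue labels on an ellipsoidal
#' brain (WM core, GM shell, CSF ventricles, optional tumor rim + necrotic
#' core), a ground-truth pH volume (class mean + smooth Gaussian-random-
#' field variation), a smooth polynomial delta-B0 field and a
#' proton-density volume.
#'
#' @param geometry configuration from [phantomGeometry()].
#' @param seed integer seed.
#' @return A \linkS4class{DigitalPhantom}.
#' @examples
#' ph <- buildPhantom(phantomGeometry(dim = c(16, 16, 16)), seed = 1)
#' @export
buildPhantom <- function(geometry = phantomGeometry(), seed = 1) {
  g <- geometry
  d <- as.integer(g$dim)
  if (any(d < 16)) stop("grid dimensions must be >= 16 in every direction")
  vs <- g$voxelSize
  set.seed(as.integer(seed))

  cx <- .axisCenters(d[1], vs[1]); cy <- .axisCenters(d[2], vs[2])
  cz <- .axisCenters(d[3], vs[3])
  center <- c(mean(range(cx)), mean(range(cy)), mean(range(cz)))
  X <- array(rep(cx, times = d[2] * d[3]), d) - center[1]
  Y <- array(rep(rep(cy, each = d[1]), times = d[3]), d) - center[2]
  Z <- array(rep(cz, each = d[1] * d[2]), d) - center[3]

  # normalized ellipsoid radius
  rn <- sqrt((X / g$brainSemiAxes[1])^2 + (Y / g$brainSemiAxes[2])^2 +
             (Z / g$brainSemiAxes[3])^2)
  labels <- array(0L, d)
  labels[rn <= 1] <- 1L                       # WM
  labels[rn <= 1 & rn > 1 - g$gmThickness] <- 2L  # GM shell

  # mirrored CSF ventricles
  for (s in c(-1, 1)) {
    vo <- g$ventricleOffset * c(s, 1, 1)
    rv <- sqrt(((X - vo[1]) / g$ventricleSemiAxes[1])^2 +
               ((Y - vo[2]) / g$ventricleSemiAxes[2])^2 +
               ((Z - vo[3]) / g$ventricleSemiAxes[3])^2)
    labels[rv <= 1 & labels == 1L] <- 3L
  }

  if (g$tumorRadius > 0) {
    tc <- g$tumorCenter
    rt <- sqrt((X - tc[1])^2 + (Y - tc[2])^2 + (Z - tc[3])^2)
    if (any(rt <= g$tumorRadius & rn > 1))
      stop("tumor placement outside the brain")
    labels[rt <= g$tumorRadius & labels %in% c(1L, 2L)] <- 4L
    labels[rt <= g$coreRadius & labels == 4L] <- 5L
  }

  classNames <- c("WM", "GM", "CSF", "tumor_rim", "necrotic_core")
  ph <- array(NA_real_, d)
  m0 <- array(0, d)
  for (i in seq_along(classNames)) {
    sel <- labels == i
    ph[sel] <- g$phByClass[[classNames[i]]]
    m0[sel] <- .classM0(classNames[i]) * 1000
  }
  if (g$phSd > 0) {
    grf <- .grf(d, g$phSmoothVox) * g$phSd
    inb <- labels > 0
    ph[inb] <- ph[inb] + grf[inb]
  }

  # smooth delta-B0: quadratic polynomial in normalized coordinates,
  # random coefficients, scaled to the requested peak amplitude in-brain
  xn <- X / max(abs(X)); yn <- Y / max(abs(Y)); zn <- Z / max(abs(Z))
  co <- stats::runif(9, -1, 1)
  db0 <- co[1] + co[2] * xn + co[3] * yn + co[4] * zn +
    co[5] * xn^2 + co[6] * yn^2 + co[7] * zn^2 +
    co[8] * xn * yn + co[9] * xn * zn
  if (g$db0Amplitude > 0) {
    peak <- max(abs(db0[labels > 0]))
    db0 <- db0 / peak * g$db0Amplitude
  } else {
    db0 <- array(0, d)
  }

  classParams <- stats::setNames(lapply(classNames, tissuePreset), classNames)
  classM0 <- stats::setNames(
    vapply(classNames, .classM0, 0) * 1000, classNames)

  new("DigitalPhantom", labels = labels, voxelSize = as.numeric(vs),
      classParams = classParams, classM0 = classM0, ph = ph,
      db0 = db0, m0 = m0, geometry = g, seed = as.numeric(seed))
}

#' Brain mask of a phantom
#'
#' The analysis mask used throughout the pipeline: brain tissue excluding
#' CSF, eroded with a 6-connected structuring element (outlier exclusion at
#' the mask boundary, as done for in vivo data near the skull).
#'
#' @param phantom a \linkS4class{DigitalPhantom}.
#' @param iterations erosion passes (default 1).
#' @return Logical 3D array.
#' @export
phantomMask <- function(phantom, iterations = 1) {
  brain <- phantom@labels > 0L
  eroded <- erodeMask(brain, iterations)
  eroded & phantom@labels != 3L
}
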