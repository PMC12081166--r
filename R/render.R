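#' Render raw CEST data from a phantom
#'
#' Per voxel, the Z-spectrum follows from the Bloch-McConnell simulator
#' using the voxel's class parameters with the amide exchange rate set from
#' the voxel's pH via [amideExchangeRate()], and with all saturation offsets
#' shifted by the voxel's delta-B0. Gaussian noise of standard deviation
#' \code{noiseSd} is added on the normalized Z scale, then the spectrum is
#' rescaled by the voxel's M0 to yield raw signal.
#'
#' For tractability the default path simulates one spectrum per (class,
#' pH-bin) combination — pH quantized at \code{phRes}, default 0.005 pH
#' units, which perturbs Z by under 1e-3 at these exchange rates — on a
#' densified offset grid, and evaluates each voxel's B0-shifted offsets by
#' monotone cubic interpolation of that cached spectrum. \code{exact = TRUE}
#' instead runs the full simulator per voxel (use only on small phantoms).
#'
#' @param phantom a \linkS4class{DigitalPhantom}.
#' @param schedule an \linkS4class{OffsetSchedule}.
#' @param noiseSd Gaussian noise sd on the normalized Z scale.
#' @param seed integer seed for the noise realization.
#' @param phRes pH quantization of the spectrum cache.
#' @param intravoxelSd intravoxel B0 dispersion in ppm passed to the
#'   simulator (see [simulateZspectrum()]; default 0: the rendered world is
#'   the spline envelope of the coherent-readout spectrum).
#' @param exact bypass the cache and simulate every voxel individually.
#' @return list with \code{cest4d} (raw 4D array, x-y-z-offset), \code{m0}
#'   (3D array) and \code{offsets}.
#' @export
renderCest <- function(phantom, schedule, noiseSd = 0.005, seed = 1,
                       phRes = 0.005, intravoxelSd = 0, exact = FALSE) {
  d <- dim(phantom@labels)
  K <- length(schedule@offsets)
  idx <- which(phantom@labels > 0L)
  lab <- phantom@labels[idx]
  ph <- phantom@ph[idx]
  db0 <- phantom@db0[idx]
  classNames <- names(phantom@classParams)

  zmat <- matrix(NA_real_, length(idx), K)
  if (exact) {
    for (v in seq_along(idx)) {
      tis <- .tissueAtPh(phantom@classParams[[lab[v]]], ph[v])
      zmat[v, ] <- zspectrumWithB0Shift(tis, schedule, db0[v],
                                        intravoxelSd = intravoxelSd)
    }
  } else {
    dense <- .denseRenderOffsets(schedule@offsets)
    denseSch <- offsetSchedule(dense, B1 = schedule@B1, tp = schedule@tp,
                               td = schedule@td,
                               nStartupPulses = schedule@nStartupPulses,
                               nPulsesPerOffset = schedule@nPulsesPerOffset,
                               B0 = schedule@B0, gamma = schedule@gamma)
    phBin <- round(ph / phRes) * phRes
    combo <- paste(lab, format(phBin, nsmall = 6), sep = "|")
    for (cb in sort(unique(combo))) {
      sel <- combo == cb
      cls <- lab[which(sel)[1]]
      pb <- phBin[which(sel)[1]]
      tis <- .tissueAtPh(phantom@classParams[[cls]], pb)
      zd <- simulateZspectrum(tis, denseSch, intravoxelSd = intravoxelSd)
      sf <- stats::splinefun(dense, zd, method = "monoH.FC")
      q <- outer(db0[sel], schedule@offsets,
                 function(b, x) x - b)  # voxel offsets shifted by -db0
      zmat[sel, ] <- matrix(sf(q), nrow = sum(sel))
    }
  }
  set.seed(as.integer(seed))
  if (noiseSd > 0)
    zmat <- zmat + matrix(stats::rnorm(length(zmat), sd = noiseSd),
                          nrow = nrow(zmat))
  m0v <- phantom@m0[idx]
  raw <- zmat * m0v

  cest4d <- array(0, c(d, K))
  n3 <- prod(d)
  for (k in seq_len(K)) cest4d[idx + (k - 1L) * n3] <- raw[, k]
  list(cest4d = cest4d, m0 = phantom@m0, offsets = schedule@offsets)
}

# tissue with the amide rate re-derived from a pH value
.tissueAtPh <- function(tissue, ph) {
  pools <- lapply(tissue@pools, function(p) {
    if (p@name == "amide") p@kExch <- amideExchangeRate(ph)
    p
  })
  tissueParams(tissue@waterR1, tissue@waterR2, pools, ph)
}

# densified offset grid for the spectrum cache: schedule offsets, a 0.1-ppm
# grid through the direct-saturation region, and padded ends so B0-shifted
# queries stay interior
.denseRenderOffsets <- function(offs, pad = 0.5) {
  sort(unique(round(c(offs, seq(-2.5, 2.5, by = 0.1),
                      min(offs) - pad, max(offs) + pad,
                      min(offs) - pad / 2, max(offs) + pad / 2), 6)))
}

#' Render T1 data from a phantom
#'
#' \code{mode = "map"} returns the per-voxel T1 directly (plus optional
#' Gaussian noise in seconds); \code{mode = "vfa"} returns the two
#' spoiled-GRE magnitude volumes of the variable-flip-angle acquisition,
#' generated with [spgrSignal()] under the (default) 4/24 degree, 16.4 ms
#' preset.
#'
#' @param phantom a \linkS4class{DigitalPhantom}.
#' @param mode \code{"map"} or \code{"vfa"}.
#' @param noiseSd Gaussian noise sd (seconds for \code{"map"}, signal units
#'   for \code{"vfa"}).
#' @param seed integer seed.
#' @param config a [vfaConfig()] (vfa mode).
#' @return For \code{"map"}: list with \code{qt1}. For \code{"vfa"}: list
#'   with \code{s1}, \code{s2} and \code{config}.
#' @export
renderT1 <- function(phantom, mode = c("map", "vfa"), noiseSd = 0, seed = 1,
                     config = vfaConfig()) {
  mode <- match.arg(mode)
  d <- dim(phantom@labels)
  t1 <- array(NA_real_, d)
  classNames <- names(phantom@classParams)
  for (i in seq_along(classNames)) {
    sel <- phantom@labels == i
    t1[sel] <- 1 / phantom@classParams[[i]]@waterR1
  }
  set.seed(as.integer(seed))
  if (mode == "map") {
    if (noiseSd > 0) {
      sel <- !is.na(t1)
      t1[sel] <- pmax(t1[sel] + stats::rnorm(sum(sel), sd = noiseSd), 1e-3)
    }
    return(list(qt1 = t1))
  }
  s1 <- array(0, d); s2 <- array(0, d)
  sel <- !is.na(t1)
  b1 <- if (length(config$b1Scale) == 1) config$b1Scale else config$b1Scale[sel]
  s1[sel] <- spgrSignal(phantom@m0[sel], t1[sel], config$fa1 * b1, config$tr)
  s2[sel] <- spgrSignal(phantom@m0[sel], t1[sel], config$fa2 * b1, config$tr)
  if (noiseSd > 0) {
    s1[sel] <- s1[sel] + stats::rnorm(sum(sel), sd = noiseSd)
    s2[sel] <- s2[sel] + stats::rnorm(sum(sel), sd = noiseSd)
  }
  list(s1 = s1, s2 = s2, config = config)
}

#' Render the low-resolution 31P pH map
#'
#' Default path: PSF-weighted average of the ground-truth pH over each
#' coarse voxel footprint (\code{psfMode "box"} = volume-weighted mean;
#' \code{"gaussian"} = FWHM equal to the coarse pitch, emulating
#' zero-filled-CSI leakage), over tissue voxels (CSF and background carry
#' no Pi signal). Optional spectral path: per coarse voxel a 31P spectrum
#' is synthesized at the PSF-weighted mixture of Pi shifts, fitted with
#' [fitPiPcrDistance()] and converted through [hhPh()] — exercising the
#' full measurement chain. \code{noiseSd} adds Gaussian noise in pH units
#' per coarse voxel on the default path (it parameterizes the spectral SNR
#' indirectly on the spectral path via \code{spectralSnr}).
#'
#' @param phantom a \linkS4class{DigitalPhantom}.
#' @param coarseVoxel 31P voxel size in mm (default 30 x 30 x 25).
#' @param psfMode \code{"box"} or \code{"gaussian"}.
#' @param spectral use the spectral synthesis-fit-convert path.
#' @param noiseSd Gaussian noise sd on the coarse pH values (pH units).
#' @param seed integer seed.
#' @param spectralSnr peak SNR of synthesized spectra on the spectral path.
#' @param cal Henderson-Hasselbalch calibration.
#' @return list with \code{ph} (coarse 3D array; NA where no brain),
#'   \code{mask}, \code{support} and \code{voxelSize}.
#' @export
renderPh31p <- function(phantom, coarseVoxel = c(30, 30, 25),
                        psfMode = c("gaussian", "box"), spectral = FALSE,
                        noiseSd = 0.01, seed = 1, spectralSnr = 100,
                        cal = hhCalibration()) {
  psfMode <- match.arg(psfMode)
  coarseVoxel <- rep(coarseVoxel, length.out = 3)
  if (any(coarseVoxel < phantom@voxelSize))
    stop("coarse voxel must be >= fine voxel in every dimension")
  tissue <- phantom@labels > 0L & phantom@labels != 3L
  set.seed(as.integer(seed))
  if (!spectral) {
    ds <- .psfDownsample(phantom@ph, tissue, phantom@voxelSize, coarseVoxel,
                         psfMode)
    if (noiseSd > 0) {
      sel <- ds$mask
      ds$values[sel] <- ds$values[sel] +
        stats::rnorm(sum(sel), sd = noiseSd)
    }
    return(ds)
  }
  # spectral path: mixture spectrum per coarse voxel, fit, convert
  shifts <- array(NA_real_, dim(phantom@ph))
  shifts[tissue] <- phToShift(phantom@ph[tissue], cal)
  # coarse geometry and per-coarse-voxel weights come from the shared PSF
  d <- dim(phantom@ph)
  nC <- as.integer(ceiling(d * phantom@voxelSize / coarseVoxel))
  Wl <- lapply(1:3, function(k)
    .psfWeights1d(d[k], phantom@voxelSize[k], nC[k], coarseVoxel[k], psfMode))
  sup <- .psfDownsample(phantom@ph, tissue, phantom@voxelSize, coarseVoxel,
                        psfMode)
  ph <- array(NA_real_, nC)
  for (j3 in seq_len(nC[3])) for (j2 in seq_len(nC[2]))
    for (j1 in seq_len(nC[1])) {
      if (!sup$mask[j1, j2, j3]) next
      w3 <- outer(outer(Wl[[1]][j1, ], Wl[[2]][j2, ]), Wl[[3]][j3, ])
      w <- w3[tissue]
      s <- shifts[tissue]
      keep <- w > max(w) * 1e-3
      # bin the shift mixture to keep the synthesis cheap
      br <- cut(s[keep], breaks = 50)
      wj <- tapply(w[keep], br, sum)
      sj <- tapply(s[keep] * w[keep], br, sum) / wj
      ok <- !is.na(wj)
      spec <- .synthesizeSpectrumMixture(sj[ok], wj[ok], snr = spectralSnr)
      fit <- fitPiPcrDistance(spec)
      ph[j1, j2, j3] <- hhPh(fit$distance, cal)
    }
  list(values = ph, mask = sup$mask, support = sup$support,
       voxelSize = coarseVoxel)
}

#' Render a full paired dataset
#'
#' One call producing everything the training and evaluation pipeline
#' consumes: raw 4D CEST + M0, the delta-B0 map, quantitative T1 (map mode;
#' optionally also the VFA GRE pair), the coarse 31P pH map, the eroded
#' brain mask (CSF excluded) and the ground-truth pH at CEST resolution.
#' Deterministic given \code{seed}; sub-renderers receive distinct seeds
#' derived from it.
#'
#' @param phantom a \linkS4class{DigitalPhantom}.
#' @param schedule an \linkS4class{OffsetSchedule}.
#' @param noiseSd Z-scale CEST noise sd.
#' @param t1NoiseSd T1 map noise sd, s.
#' @param ph31pNoiseSd coarse pH noise sd, pH units.
#' @param coarseVoxel 31P voxel size, mm.
#' @param psfMode PSF mode for the 31P rendering.
#' @param includeVfa also render the VFA GRE pair.
#' @param erodeIterations erosion passes for the analysis mask.
#' @param seed integer seed.
#' @return An \linkS4class{AcquiredDataset}.
#' @export
renderDataset <- function(phantom, schedule = schedulePreset("paper_3T"),
                          noiseSd = 0.005, t1NoiseSd = 0.02,
                          ph31pNoiseSd = 0.01,
                          coarseVoxel = c(30, 30, 25),
                          psfMode = c("gaussian", "box"),
                          includeVfa = FALSE, erodeIterations = 1,
                          seed = 1) {
  psfMode <- match.arg(psfMode)
  seed <- as.integer(seed)
  cest <- renderCest(phantom, schedule, noiseSd = noiseSd, seed = seed)
  t1 <- renderT1(phantom, "map", noiseSd = t1NoiseSd, seed = seed + 1L)
  vfa <- if (includeVfa)
    renderT1(phantom, "vfa", noiseSd = 0, seed = seed + 2L) else list()
  p31 <- renderPh31p(phantom, coarseVoxel = coarseVoxel, psfMode = psfMode,
                     noiseSd = ph31pNoiseSd, seed = seed + 3L)
  mask <- phantomMask(phantom, erodeIterations)
  qt1 <- t1$qt1
  qt1[is.na(qt1)] <- 0
  new("AcquiredDataset",
      cest4d = cest$cest4d, m0 = phantom@m0, db0 = phantom@db0,
      qt1 = qt1, vfaPair = vfa,
      ph31p = list(ph = p31$values, mask = p31$mask,
                   voxelSize = p31$voxelSize),
      mask = mask, truthPh = phantom@ph, schedule = schedule,
      voxelSize = phantom@voxelSize, seed = as.numeric(seed))
}
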