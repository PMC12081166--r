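# digital phantom and renderers

test_that("phantom construction is deterministic and anatomically ordered", {
  g <- tinyGeometry()
  p1 <- buildPhantom(g, seed = 7)
  p2 <- buildPhantom(g, seed = 7)
  expect_identical(phVolume(p1), phVolume(p2))
  expect_identical(labelVolume(p1), labelVolume(p2))
  expect_identical(p1@db0, p2@db0)
  lab <- labelVolume(p1)
  expect_true(all(sort(unique(as.vector(lab))) %in% 0:5))
  # tumor pH is elevated over white matter
  expect_gt(mean(phVolume(p1)[lab == 4]), mean(phVolume(p1)[lab == 1]))
  # pH defined wherever label != background
  expect_true(all(is.finite(phVolume(p1)[lab > 0])))
})

test_that("db0 amplitude zero yields an all-zero field", {
  p <- buildPhantom(tinyGeometry(db0Amplitude = 0), seed = 1)
  expect_true(all(p@db0 == 0))
})

test_that("tumor placement outside the brain is rejected", {
  expect_error(buildPhantom(tinyGeometry(tumorCenter = c(24, 0, 0)),
                            seed = 1),
               "outside the brain")
})

test_that("mask erosion behaves like a 6-connected erosion", {
  m <- array(TRUE, c(5, 5, 5))
  e <- erodeMask(m, 1)
  expect_equal(sum(e), 27)
  expect_true(all(e[2:4, 2:4, 2:4]))
  expect_identical(erodeMask(array(FALSE, c(4, 4, 4)), 1),
                   array(FALSE, c(4, 4, 4)))
  expect_identical(erodeMask(m, 0), m)
})

test_that("rendered CEST spectra respect class, pH and M0 structure", {
  p <- buildPhantom(tinyGeometry(phSd = 0, db0Amplitude = 0), seed = 1)
  sch <- smallSchedule(offsets = c(-3.5, 0, 3.5))
  rc <- renderCest(p, sch, noiseSd = 0, seed = 1)
  lab <- labelVolume(p)
  # equal tissue parameters, no noise, no db0 -> identical spectra
  wmIdx <- which(lab == 1L)[1:2]
  n3 <- length(lab)
  s1 <- rc$cest4d[wmIdx[1] + (0:2) * n3]
  s2 <- rc$cest4d[wmIdx[2] + (0:2) * n3]
  expect_equal(s1, s2, tolerance = 1e-12)
  # background (m0 = 0) renders zero signal
  bgIdx <- which(lab == 0L)[1]
  expect_equal(rc$cest4d[bgIdx + (0:2) * n3], c(0, 0, 0))
})

test_that("higher pH voxels show a larger amide label effect", {
  g <- tinyGeometry(phSd = 0, db0Amplitude = 0,
                    phByClass = c(WM = 7.0, GM = 7.2, CSF = 7.0,
                                  tumor_rim = 7.2, necrotic_core = 7.25))
  # give GM identical relaxation/pools to WM so only pH differs
  p <- buildPhantom(g, seed = 1)
  sch <- offsetSchedule(c(-3.5, 3.5), B1 = 1, nStartupPulses = 5)
  wm <- tissuePreset("WM", pH = 7.0)
  z70 <- simulateZspectrum(cestph:::.tissueAtPh(wm, 7.0), sch)
  z72 <- simulateZspectrum(cestph:::.tissueAtPh(wm, 7.2), sch)
  expect_gt(1 - z72[2], 1 - z70[2])
})

test_that("cached rendering agrees with exact per-voxel simulation", {
  p <- buildPhantom(tinyGeometry(), seed = 2)
  sch <- offsetSchedule(c(-4, -3.5, 3.5, 4), B1 = 1, nStartupPulses = 3)
  rc <- renderCest(p, sch, noiseSd = 0, seed = 1)
  lab <- labelVolume(p)
  idx <- c(which(lab == 1L)[1], which(lab == 2L)[1], which(lab == 4L)[1])
  n3 <- length(lab)
  for (v in idx) {
    tis <- cestph:::.tissueAtPh(p@classParams[[lab[v]]], phVolume(p)[v])
    zExact <- zspectrumWithB0Shift(tis, sch, p@db0[v])
    zCache <- rc$cest4d[v + (seq_along(offsets(sch)) - 1L) * n3] / p@m0[v]
    # pH binning (0.005), spline evaluation and residual nutation-sideband
    # aliasing bound the cache error at the 1e-2 level away from water
    expect_lt(max(abs(zExact - zCache)), 1e-2)
  }
})

test_that("T1 rendering is exact in map mode and invertible in VFA mode", {
  p <- buildPhantom(tinyGeometry(), seed = 1)
  lab <- labelVolume(p)
  t1map <- renderT1(p, "map", noiseSd = 0)$qt1
  expect_equal(unique(t1map[lab == 1L]), 1 / p@classParams$WM@waterR1)
  expect_gt(unique(t1map[lab == 3L]), unique(t1map[lab == 1L]))  # CSF > WM
  vfa <- renderT1(p, "vfa", noiseSd = 0)
  fit <- vfaFit(vfa$s1, vfa$s2, vfa$config)
  inb <- lab > 0L
  expect_lt(max(abs(fit$t1[inb] - t1map[inb]) / t1map[inb]), 1e-6)
})

test_that("31P rendering conserves uniform pH and averages mixtures", {
  g <- tinyGeometry(phSd = 0,
                    phByClass = c(WM = 7, GM = 7, CSF = 7,
                                  tumor_rim = 7, necrotic_core = 7))
  p <- buildPhantom(g, seed = 1)
  r <- renderPh31p(p, coarseVoxel = c(15, 15, 16), psfMode = "box",
                   noiseSd = 0)
  expect_equal(unique(r$values[r$mask]), 7, tolerance = 1e-12)
  # half 7.0 / half 7.2 at equal volumes -> 7.1 under a box PSF
  p2 <- buildPhantom(g, seed = 1)
  d <- dim(p2@ph)
  ph2 <- array(7.0, d); ph2[1:(d[1] / 2), , ] <- 7.2
  p2@ph <- ph2
  p2@labels <- array(1L, d)  # all WM so every voxel counts
  r2 <- renderPh31p(p2, coarseVoxel = p2@voxelSize * d, psfMode = "box",
                    noiseSd = 0)
  expect_equal(as.numeric(r2$values[1, 1, 1]), 7.1, tolerance = 1e-12)
})

test_that("gaussian PSF leaks more surround into a sharp boundary than box", {
  # step phantom: left half 7.0, right half 7.2; coarse voxel centered on
  # the 7.2 side near the boundary sees more 7.0 under the gaussian PSF
  d <- c(20, 8, 8)
  p <- buildPhantom(tinyGeometry(), seed = 1)
  ph <- array(7.0, d); ph[11:20, , ] <- 7.2
  vol <- list()
  for (mode in c("box", "gaussian")) {
    vol[[mode]] <- downsampleToTarget(ph, c(3, 3, 4), c(15, 24, 32),
                                      psfMode = mode)$values
  }
  # coarse cell 3 along x covers fine cells 11..15 (pure 7.2 under box)
  expect_equal(vol$box[3, 1, 1], 7.2, tolerance = 1e-12)
  expect_lt(vol$gaussian[3, 1, 1], vol$box[3, 1, 1])
})

test_that("31P spectral path reproduces the direct PSF average", {
  g <- tinyGeometry(phSd = 0.01)
  p <- buildPhantom(g, seed = 5)
  direct <- renderPh31p(p, coarseVoxel = c(20, 20, 32), psfMode = "box",
                        noiseSd = 0)
  spectral <- renderPh31p(p, coarseVoxel = c(20, 20, 32), psfMode = "box",
                          spectral = TRUE, spectralSnr = Inf)
  sel <- direct$mask & spectral$mask
  expect_gt(sum(sel), 0)
  # HH conversion is nonlinear, so mixture-fit vs mean-of-pH differ at
  # second order; they must agree closely at these narrow pH spreads
  expect_lt(max(abs(direct$values[sel] - spectral$values[sel])), 0.01)
})

test_that("paired dataset geometry reproduces the resolution gain", {
  p <- buildPhantom(tinyGeometry(), seed = 1)
  ds <- renderDataset(p, schedule = smallSchedule(), seed = 1,
                      coarseVoxel = c(30, 30, 25))
  expect_equal(prod(ds@ph31p$voxelSize) / prod(voxelSize(ds)), 625)
  expect_equal(dim(ds@cest4d)[4], length(offsets(ds@schedule)))
  # rendering is deterministic under a fixed seed
  ds2 <- renderDataset(p, schedule = smallSchedule(), seed = 1,
                       coarseVoxel = c(30, 30, 25))
  expect_identical(ds@cest4d, ds2@cest4d)
  expect_identical(ds@ph31p$ph, ds2@ph31p$ph)
})
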