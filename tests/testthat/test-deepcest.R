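# feature assembly, standardization, GNLL, training, prediction, attack

test_that("feature assembly yields one fixed-dimension row per voxel", {
  wm <- tissuePreset("WM")
  sch <- schedulePreset("paper_3T")
  z <- simulateZspectrum(wm, sch)
  d <- c(10, 1, 1)
  zarr <- array(rep(z, each = 10), c(d, length(z)))
  zv <- new("ZSpectrumVolume", offsets = offsets(sch), z = zarr,
            voxelSize = c(3, 3, 4), mask = array(TRUE, d),
            extrapolated = array(FALSE, d))
  blk <- mtrAsymBlock(zv)
  qt1 <- array(1.1, d)
  ft <- assembleFeatures(zv, blk, qt1, array(TRUE, d))
  expect_equal(nrow(ft$x), 10)
  expect_equal(ncol(ft$x), 49 + 11 + 1)
  expect_equal(ft$dropped, 0)
  # a NaN T1 drops that voxel and leaves the others untouched
  qt1[3, 1, 1] <- NaN
  ft2 <- assembleFeatures(zv, blk, qt1, array(TRUE, d))
  expect_equal(nrow(ft2$x), 9)
  expect_equal(ft2$dropped, 1)
  expect_equal(ft2$voxels, setdiff(ft$voxels, 3))
  expect_equal(ft2$x[, 1:60], ft$x[-3, 1:60])
})

test_that("standardization is exact, invertible and guards constants", {
  set.seed(5)
  x <- matrix(rnorm(200, mean = 3, sd = 2), 50, 4)
  s <- standardizeFeatures(x)
  expect_equal(unname(colMeans(s$x)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(s$x, 2, sd)), rep(1, 4), tolerance = 1e-9)
  # applying frozen stats, then inverting, is the identity
  s2 <- standardizeFeatures(x, s$stats)
  expect_equal(s2$x, s$x)
  back <- sweep(sweep(s$x, 2, s$stats$sd, "*"), 2, s$stats$mean, "+")
  expect_equal(back, x, tolerance = 1e-12)
  # constant column: pinned sd, zero output, warning
  xc <- cbind(x, 7)
  expect_warning(sc <- standardizeFeatures(xc), "zero-variance")
  expect_true(all(sc$x[, 5] == 0))
  expect_equal(unname(sc$stats$sd[5]), 1)
})

test_that("the GNLL loss matches its closed form and minimizers", {
  expect_equal(gnllLoss(1, 1, 1), 0)
  expect_equal(gnllLoss(0, 2, 1), 0.5 * (log(2) + 1 / 2))
  # residual zero: loss is monotone in sigma2, minimized at the floor
  s2 <- c(1e-6, 1e-4, 1e-2, 1)
  losses <- vapply(s2, function(s) gnllLoss(0, s, 0), 0)
  expect_true(all(diff(losses) > 0))
  # fixed residual: analytic minimizer sigma2* = (y - mu)^2
  r2 <- 0.3^2
  grid <- seq(0.01, 0.5, by = 0.001)
  lg <- vapply(grid, function(s) gnllLoss(0, s, 0.3), 0)
  expect_equal(grid[which.min(lg)], r2, tolerance = 2e-3)
  # below-floor variances are clamped
  expect_equal(gnllLoss(0, 1e-12, 0, varianceFloor = 1e-6),
               gnllLoss(0, 1e-6, 0, varianceFloor = 1e-6))
})

test_that("training is bitwise deterministic under a fixed seed", {
  set.seed(99)
  x <- matrix(rnorm(600), 200, 3)
  y <- 7 + 0.1 * x[, 1] + rnorm(200, sd = 0.01)
  cfg <- netConfig(epochs = 20, batchSize = 64, seed = 4)
  m1 <- trainDeepCest(x, y, cfg)
  m2 <- trainDeepCest(x, y, cfg)
  expect_identical(m1@weights, m2@weights)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
})

test_that("the network fits a noiseless affine toy within 200 epochs", {
  set.seed(21)
  x <- matrix(rnorm(15000), 5000, 3)
  y <- 7.1 + 0.08 * x[, 2]          # affine in one feature, no noise
  cfg <- netConfig(epochs = 200, batchSize = 128, seed = 1)
  m <- trainDeepCest(x, y, cfg)
  h <- trainingHistory(m)
  expect_lt(min(h$valRmse), 0.005)
})

test_that("prediction is voxel-wise, destandardized and floor-bounded", {
  set.seed(31)
  x <- matrix(rnorm(1500), 500, 3)
  y <- 7 + 0.05 * x[, 1] + rnorm(500, sd = 0.02)
  m <- trainDeepCest(x, y, netConfig(epochs = 50, batchSize = 128, seed = 2))
  pm <- cestph:::.predictMatrix(m, x)
  expect_equal(dim(pm), c(500L, 2L))
  # permuting rows permutes outputs identically (up to BLAS-blocking
  # floating-point noise)
  perm <- sample(500)
  expect_equal(cestph:::.predictMatrix(m, x[perm, ]), pm[perm, ],
               tolerance = 1e-12)
  # sigma respects the propagated variance floor
  floorSigma <- sqrt(m@config$varianceFloor) * m@stats$target$sd
  expect_true(all(pm[, "sigma"] >= floorSigma))
  expect_error(cestph:::.predictMatrix(m, x[, 1:2]), "dimension mismatch")
})

test_that("model checkpoints round-trip losslessly through JSON", {
  set.seed(8)
  x <- matrix(rnorm(300), 100, 3)
  y <- 7 + 0.1 * x[, 3]
  m <- trainDeepCest(x, y, netConfig(epochs = 5, batchSize = 32, seed = 3))
  tf <- withr::local_tempfile(fileext = ".json")
  writeModelCheckpoint(m, tf)
  m2 <- readModelCheckpoint(tf)
  expect_equal(m2@weights, m@weights, tolerance = 1e-12)
  expect_equal(cestph:::.predictMatrix(m2, x),
               cestph:::.predictMatrix(m, x), tolerance = 1e-12)
})

test_that("divergent training aborts with a diagnostic", {
  set.seed(12)
  x <- matrix(rnorm(300), 100, 3)
  y <- rnorm(100)
  cfg <- netConfig(epochs = 5, batchSize = 32, seed = 1, lr = Inf)
  expect_error(trainDeepCest(x, y, cfg), "diverged|non-finite")
})

test_that("the T1 attack changes nothing outside the ROI", {
  # small end-to-end fixture: phantom -> features -> short training
  p <- buildPhantom(tinyGeometry(), seed = 6)
  sch <- offsetSchedule(sort(unique(c(seq(-4, 4, 1), seq(3, 4, 0.1),
                                      seq(-4, -3, 0.1)))),
                        B1 = 1, nStartupPulses = 3)
  ds <- renderDataset(p, schedule = sch, seed = 6)
  tt <- trainingTable(ds)
  m <- trainDeepCest(tt$features, tt$targets,
                     netConfig(epochs = 30, seed = 1))
  pr <- tt$processed
  roi <- array(FALSE, dim(pr$mask))
  roi[which(pr$mask & labelVolume(p) == 1L)[1:20]] <- TRUE
  res <- t1Attack(m, pr$zvol, pr$asym, pr$qt1, pr$mask, roi, fakeT1 = 1.8)
  outside <- res$baseline@mask & !roi
  expect_true(all(res$deltaMean[outside] == 0))
  # fake T1 equal to the original is a strict no-op
  resSame <- t1Attack(m, pr$zvol, pr$asym, pr$qt1, pr$mask, roi,
                      fakeT1 = unique(pr$qt1[roi])[1])
  expect_true(all(abs(resSame$deltaMean[roi][
    pr$qt1[roi] == unique(pr$qt1[roi])[1]]) == 0))
  expect_error(t1Attack(m, pr$zvol, pr$asym, pr$qt1, pr$mask,
                        array(FALSE, dim(pr$mask)), 1.8), "empty ROI")
})

test_that("end-to-end recovery reaches the voxel-wise information ceiling", {
  # On the default phantom world the coarse 31P targets carry partial-volume
  # structure that depends on where a voxel sits inside its 625x-larger
  # 31P cell, which no voxel-wise feature can encode. The reachable ceiling
  # is the oracle E[target | class, fine pH]; the trained network must hold
  # the RMSE contract and come close to that ceiling in correlation.
  run <- acceptanceRun()
  expect_lte(run$heldout$rmse, 0.04)
  tt <- trainingTable(run$dataset, run$processed)
  lab <- labelVolume(run$phantom)[tt$voxels]
  finePh <- phVolume(run$phantom)[tt$voxels]
  grp <- paste(lab, round(finePh / 0.01))
  oracle <- tapply(tt$targets, grp, mean)[grp]
  rOracle <- cor(oracle, tt$targets)
  expect_gte(run$heldout$r, 0.85 * rOracle)
})
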