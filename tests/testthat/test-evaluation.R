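# multi-resolution evaluation statistics

test_that("rmse matches hand-computed values", {
  a <- array(c(7.0, 7.1), c(2, 1, 1))
  b <- array(c(7.1, 7.0), c(2, 1, 1))
  expect_equal(rmse(a, a), 0)
  expect_equal(rmse(a, b), 0.1)
  expect_equal(rmse(a, a + 0.04), 0.04, tolerance = 1e-12)
  expect_error(rmse(a, b, mask = array(FALSE, c(2, 1, 1))), "empty")
})

test_that("SSIM is 1 on identical maps, symmetric, negative on inversion", {
  set.seed(17)
  a <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  a <- cestph:::.gaussSmooth3d(a, 1)
  expect_equal(ssim(a, a), 1, tolerance = 1e-9)
  b <- a + array(rnorm(length(a), sd = 0.5 * sd(a)), dim(a))
  # with a fixed dynamic range the index is symmetric in its arguments
  L <- diff(range(a))
  expect_equal(ssim(a, b, dynamicRange = L), ssim(b, a, dynamicRange = L),
               tolerance = 1e-12)
  expect_lt(ssim(a, b), 1)
  # zero-local-mean anticorrelated pattern scores negative: the luminance
  # term degenerates to C1 > 0 while the structure term goes negative
  idx <- expand.grid(1:16, 1:16, 1:3)
  cb <- array(ifelse((idx[, 1] + idx[, 2]) %% 2 == 0, 1, -1), c(16, 16, 3))
  expect_lt(ssim(cb, -cb, dynamicRange = 2), 0)
  # 3D-window variant agrees qualitatively
  expect_equal(ssim(a, a, mode3d = TRUE), 1, tolerance = 1e-9)
})

test_that("correlation handles affine, inverted and independent inputs", {
  set.seed(23)
  a <- array(rnorm(4000), c(40, 10, 10))
  co <- mapCorrelation(a, 2 * a + 1)
  expect_equal(co$r, 1, tolerance = 1e-12)
  expect_equal(co$r2, 1, tolerance = 1e-12)
  expect_equal(mapCorrelation(a, -a)$r, -1, tolerance = 1e-12)
  b <- array(rnorm(4000), dim(a))          # independent: null correlation
  expect_lt(abs(mapCorrelation(a, b)$r), 0.1)
  expect_error(mapCorrelation(a, array(1, dim(a))), "constant")
})

test_that("Bland-Altman statistics match the textbook formulas", {
  a <- array(7, c(3, 1, 1))
  ba <- blandAltman(a, a)
  expect_equal(unlist(ba[c("meanDiff", "sd", "loaLow", "loaHigh")]),
               c(meanDiff = 0, sd = 0, loaLow = 0, loaHigh = 0))
  ba2 <- blandAltman(a + 0.01, a)
  expect_equal(ba2$meanDiff, 0.01)
  expect_equal(ba2$sd, 0)
  # hand-checked: d = {-0.02, 0, 0.02} -> sd 0.02, limits +/- 0.0392
  b <- array(c(7 - 0.02, 7, 7 + 0.02), c(3, 1, 1))
  ba3 <- blandAltman(b, a)
  expect_equal(ba3$meanDiff, 0)
  expect_equal(ba3$sd, 0.02)
  expect_equal(ba3$loaHigh, 1.96 * 0.02)
  expect_equal(ba3$loaLow, -1.96 * 0.02)
  # report invariant: limits = mean +/- 1.96 sd, r2 <= 1
  rep <- evalReport(b, a + array(rnorm(3, sd = 0.01), c(3, 1, 1)))
  expect_equal(rep$baLoaHigh, rep$baMeanDiff + 1.96 * rep$baSd)
  expect_equal(rep$baLoaLow, rep$baMeanDiff - 1.96 * rep$baSd)
  expect_lte(rep$r2, 1)
})

test_that("PSF downsampling conserves constants and averages blocks", {
  v <- array(5, c(8, 8, 8))
  ds <- downsampleToTarget(v, c(1, 1, 1), c(2, 2, 2), "box")
  expect_true(all(ds$values == 5))
  # checkerboard of a, b -> uniform (a + b) / 2 under 2x box averaging
  idx <- expand.grid(1:8, 1:8, 1:8)
  cb <- array(ifelse((idx[, 1] + idx[, 2] + idx[, 3]) %% 2 == 0, 2, 4),
              c(8, 8, 8))
  dcb <- downsampleToTarget(cb, c(1, 1, 1), c(2, 2, 2), "box")
  expect_true(all(abs(dcb$values - 3) < 1e-12))
  # interior mean conservation at 1e-12
  set.seed(3)
  r <- array(runif(512), c(8, 8, 8))
  dr <- downsampleToTarget(r, c(1, 1, 1), c(4, 4, 4), "box")
  expect_equal(dr$values[1, 1, 1], mean(r[1:4, 1:4, 1:4]),
               tolerance = 1e-12)
  expect_error(downsampleToTarget(r, c(2, 2, 2), c(1, 1, 1)), ">=")
})

test_that("evaluation downsampling is bit-identical to the 31P render path", {
  p <- buildPhantom(tinyGeometry(), seed = 9)
  tissue <- labelVolume(p) > 0L & labelVolume(p) != 3L
  rp <- renderPh31p(p, coarseVoxel = c(30, 30, 25), psfMode = "gaussian",
                    noiseSd = 0)
  dt <- downsampleToTarget(phVolume(p), voxelSize(p), c(30, 30, 25),
                           "gaussian", mask = tissue)
  expect_identical(rp$values, dt$values)
  expect_identical(rp$mask, dt$mask)
})

test_that("nearest-neighbour upsampling inverts block structure", {
  lo <- array(1:8, c(2, 2, 2))
  hi <- upsampleNearest(lo, c(2, 2, 2), c(4, 4, 4), c(1, 1, 1))
  expect_equal(hi[1, 1, 1], 1)
  expect_equal(hi[4, 4, 4], 8)
  expect_true(all(hi[1:2, 1:2, 1:2] == 1))
})

test_that("the metric ladder ranks self-derived truth first and noise last", {
  set.seed(13)
  d <- c(24, 24, 8)
  pred <- 7 + cestph:::.gaussSmooth3d(array(rnorm(prod(d)), d), 2) * 0.1
  mask <- array(TRUE, d)
  hiV <- c(3, 3, 4); loV <- c(12, 12, 8)
  truth <- downsampleToTarget(pred, hiV, loV, "box", mask = mask)$values
  noiseMap <- array(rnorm(prod(d)), d)
  lad <- metricLadder(pred, list(noise = noiseMap,
                                 affine = 3 * pred - 12),
                      truth, hiV, loV, mask, psfMode = "box")
  expect_equal(lad$metric[1], "prediction")
  expect_equal(lad$r[lad$metric == "prediction"], 1, tolerance = 1e-9)
  expect_equal(lad$metric[nrow(lad)], "noise")
  # z-normalization makes the ladder invariant to affine rescaling
  expect_equal(lad$r[lad$metric == "affine"], 1, tolerance = 1e-9)
})

test_that("statistics are invariant to voxel enumeration order", {
  set.seed(29)
  a <- array(rnorm(60) + 7, c(60, 1, 1))
  b <- a + array(rnorm(60, sd = 0.05), c(60, 1, 1))
  perm <- sample(60)
  ap <- array(a[perm], dim(a)); bp <- array(b[perm], dim(b))
  expect_equal(rmse(ap, bp), rmse(a, b))
  expect_equal(mapCorrelation(ap, bp)$r, mapCorrelation(a, b)$r)
  expect_equal(blandAltman(ap, bp)$sd, blandAltman(a, b)$sd)
})

test_that("SSIM agrees with an independent reference implementation", {
  # expected value computed once with scikit-image's structural_similarity
  # (gaussian_weights=True, sigma=1.5, use_sample_covariance=False,
  # data_range = range of b) on this exact fixture; the implementations
  # differ only in edge handling (crop vs in-mask renormalization)
  set.seed(17)
  a2 <- matrix(rnorm(32 * 32), 32, 32)
  k <- exp(-(-3:3)^2 / 4)
  a2 <- t(apply(apply(a2, 2, function(cc) filter(cc, k / sum(k),
                                                 circular = TRUE)),
                1, function(rr) filter(rr, k / sum(k), circular = TRUE)))
  b2 <- a2 + matrix(rnorm(1024, sd = 0.3 * sd(a2)), 32, 32)
  L <- diff(range(b2))
  mine <- ssim(array(a2, c(32, 32, 1)), array(b2, c(32, 32, 1)),
               dynamicRange = L)
  expect_equal(mine, 0.8555604672269754, tolerance = 0.02)
})
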