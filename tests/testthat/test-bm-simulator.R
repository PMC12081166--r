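# Bloch-McConnell simulator: exchange-rate law, pulse-train propagation,
# closed-form and symmetry oracles

test_that("amide exchange rate follows the base-catalyzed law", {
  expect_equal(amideExchangeRate(7.0, kRef = 30, pHRef = 7.0), 30)
  expect_equal(amideExchangeRate(8.0, kRef = 30, pHRef = 7.0), 300)
  # direct evaluation of the closed form at pH 7.2
  expect_equal(amideExchangeRate(7.2, kRef = 30, pHRef = 7.0),
               30 * 10^0.2, tolerance = 1e-12)
  # strictly increasing
  ph <- seq(6, 8, length.out = 50)
  expect_true(all(diff(amideExchangeRate(ph)) > 0))
  expect_error(amideExchangeRate(5.5), "range")
  expect_error(amideExchangeRate(8.2), "range")
})

test_that("no saturation and far off-resonance leave water untouched", {
  w <- waterTissue()
  expect_equal(simulateZspectrum(w, smallSchedule(B1 = 0)),
               rep(1, 9), tolerance = 1e-12)
  zFar <- simulateZspectrum(w, smallSchedule(offsets = 300))
  expect_equal(zFar, 1, tolerance = 1e-3)
})

test_that("continuous-wave limit matches the analytic steady state", {
  w <- waterTissue(t1 = 1.1, t2 = 0.07)
  sch <- offsetSchedule(seq(-6, 6, length.out = 20), B1 = 1, tp = 20,
                        td = 0, nStartupPulses = 0, nPulsesPerOffset = 1)
  z <- simulateZspectrum(w, sch)
  zss <- cwSteadyStateOracle(sch@offsets, 1, w@waterR1, w@waterR2)
  expect_lt(max(abs(z - zss) / zss), 0.01)
})

test_that("Z stays within [0, 1] over randomized physical parameter sets", {
  set.seed(42)
  sch <- smallSchedule()
  for (i in 1:15) {
    tis <- tissueParams(
      waterR1 = runif(1, 0.2, 2), waterR2 = runif(1, 2, 30),
      pools = list(Pool("amide", 3.5, runif(1, 0, 5e-3), R1 = 1,
                        R2 = runif(1, 10, 60), kExch = runif(1, 0, 300)),
                   Pool("MT", -2.4, runif(1, 0, 0.15), R1 = 1,
                        R2 = runif(1, 1e4, 2e5), kExch = runif(1, 10, 60))))
    z <- simulateZspectrum(tis, sch)
    expect_true(all(z >= 0 & z <= 1))
  }
})

test_that("amide label effect grows with amide fraction", {
  sch <- offsetSchedule(3.5, B1 = 1, nStartupPulses = 5)
  eff <- vapply(c(0, 5e-4, 1e-3, 2e-3, 4e-3), function(fb) {
    tis <- tissueParams(1 / 1.1, 1 / 0.07,
                        list(Pool("amide", 3.5, fb, R2 = 30, kExch = 50)))
    1 - simulateZspectrum(tis, sch)
  }, 0)
  expect_true(all(diff(eff) > 0))
})

test_that("zero exchange and zero fractions reduce to the single pool", {
  sch <- smallSchedule()
  w <- waterTissue()
  z1 <- simulateZspectrum(w, sch)
  tis <- tissueParams(w@waterR1, w@waterR2,
                      list(Pool("amide", 3.5, 0, R2 = 30, kExch = 0),
                           Pool("NOE", -3.5, 0, R2 = 40, kExch = 0)))
  expect_equal(simulateZspectrum(tis, sch), z1, tolerance = 1e-12)
})

test_that("symmetric pool placement gives zero asymmetry", {
  tis <- tissueParams(1, 10,
                      list(Pool("a", 2, 1e-3, R2 = 30, kExch = 50),
                           Pool("b", -2, 1e-3, R2 = 30, kExch = 50)))
  offs <- c(-3, -2, -1, 1, 2, 3)
  z <- simulateZspectrum(tis, offsetSchedule(offs, nStartupPulses = 3))
  expect_equal(z[1:3], rev(z[4:6]), tolerance = 1e-6)
})

test_that("a B0 offset moves the spectral minimum accordingly", {
  w <- waterTissue()
  sch <- offsetSchedule(seq(-2, 2, 0.1), B1 = 1, nStartupPulses = 3)
  z0 <- simulateZspectrum(w, sch)
  zs <- zspectrumWithB0Shift(w, sch, db0 = 0)
  expect_identical(zs, z0)
  zs <- zspectrumWithB0Shift(w, sch, db0 = 0.5)
  expect_equal(sch@offsets[which.min(zs)], 0.5, tolerance = 0.051)
  expect_error(zspectrumWithB0Shift(w, sch, db0 = 3), "db0")
})

test_that("intravoxel B0 dispersion suppresses nutation sidebands", {
  # coherent pulsed readout ripples at ~0.03 ppm period; the smeared
  # spectrum must be smooth (small second differences on a 0.1 ppm grid)
  w <- waterTissue(t1 = 1.8, t2 = 0.25)  # long T2: worst-case ripples
  sch <- offsetSchedule(seq(1, 2, 0.05), B1 = 1, nStartupPulses = 3)
  zRaw <- simulateZspectrum(w, sch)
  zSm <- simulateZspectrum(w, sch, intravoxelSd = 0.02)
  rough <- function(z) max(abs(diff(diff(z))))
  expect_lt(rough(zSm), rough(zRaw) / 20)
})

test_that("the 3T preset encodes the acquisition schedule", {
  sch <- schedulePreset("paper_3T")
  expect_length(offsets(sch), 49)
  expect_equal(range(offsets(sch)), c(-8, 8))
  expect_true(all(seq(3, 4, 0.1) %in% offsets(sch)))
  expect_true(all(seq(-4, -3, 0.1) %in% offsets(sch)))
  expect_equal(sch@B1, 1)
  expect_equal(sch@tp, 0.25)
  expect_equal(sch@td, 0.25)
  expect_equal(sch@nStartupPulses, 10)
  # config round-trip
  tf <- withr::local_tempfile(fileext = ".json")
  writeSchedule(sch, tf)
  sch2 <- readSchedule(tf)
  expect_equal(offsets(sch2), offsets(sch))
  expect_equal(sch2@B0, sch@B0)
})

test_that("tissue configuration round-trips through JSON", {
  tis <- tissuePreset("tumor_rim")
  tf <- withr::local_tempfile(fileext = ".json")
  writeTissue(tis, tf)
  tis2 <- readTissue(tf)
  expect_equal(tis2@waterR1, tis@waterR1)
  expect_equal(tis2@pH, tis@pH)
  expect_equal(length(tis2@pools), length(tis@pools))
  expect_equal(tis2@pools[[1]]@kExch, tis@pools[[1]]@kExch)
})

test_that("invalid parameters are rejected", {
  expect_error(Pool("x", 3.5, -1), "fraction")
  expect_error(tissueParams(0, 10), "relaxation")
  expect_error(tissueParams(1, 10, pH = 8.5), "pH")
  expect_error(offsetSchedule(c(0, NA)), "finite")
})
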