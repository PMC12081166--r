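# shared fixtures: all synthetic data are generated in code at test time

# small offset schedule for cheap simulator tests
smallSchedule <- function(offsets = seq(-4, 4, 1), B1 = 1) {
  offsetSchedule(offsets, B1 = B1, tp = 0.25, td = 0.25,
                 nStartupPulses = 2, nPulsesPerOffset = 1)
}

# pure-water tissue
waterTissue <- function(t1 = 1.1, t2 = 0.07) tissueParams(1 / t1, 1 / t2)

# independent closed-form oracle: continuous-wave single-pool steady state
# Z_ss = R1 cos^2(theta) / (R1 cos^2(theta) + R2 sin^2(theta)),
# tan(theta) = omega1 / delta_omega
cwSteadyStateOracle <- function(offsetsPpm, B1, R1, R2, B0 = 3,
                                gamma = 42.577) {
  om1 <- 2 * pi * gamma * B1
  dw <- offsetsPpm * 2 * pi * gamma * B0
  c2 <- dw^2 / (dw^2 + om1^2)
  s2 <- om1^2 / (dw^2 + om1^2)
  R1 * c2 / (R1 * c2 + R2 * s2)
}

# a small but structurally complete phantom (brain + GM shell + ventricle +
# tumor rim/core), cheap enough for per-test rendering
tinyGeometry <- function(...) {
  base <- list(dim = c(20, 20, 16), voxelSize = c(3, 3, 4),
               brainSemiAxes = c(26, 26, 28),
               ventricleSemiAxes = c(6, 6, 6),
               ventricleOffset = c(8, 0, 0),
               tumorCenter = c(12, 4, 2), tumorRadius = 9,
               coreRadius = 4)
  do.call(phantomGeometry, utils::modifyList(base, list(...)))
}

# wrap a bare spectrum matrix (voxels x offsets) into a ZSpectrumVolume on
# a 1 x nvox x 1 grid
zvolFromMatrix <- function(zm, offsets, voxelSize = c(3, 3, 4)) {
  nv <- nrow(zm)
  z <- array(NA_real_, c(nv, 1, 1, ncol(zm)))
  z[, 1, 1, ] <- zm
  mask <- array(TRUE, c(nv, 1, 1))
  new("ZSpectrumVolume", offsets = offsets, z = z,
      voxelSize = as.numeric(voxelSize), mask = mask,
      extrapolated = array(FALSE, c(nv, 1, 1)))
}
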