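#' Exchange pool definition
#'
#' A single proton pool in the Bloch-McConnell model: a resonance at
#' \code{chemicalShift} ppm from water, holding a proton fraction relative to
#' the water pool (water = 1), longitudinal/transverse relaxation rates and
#' the chemical exchange rate towards water.
#'
#' @slot name pool label, e.g. \code{"amide"}.
#' @slot chemicalShift resonance offset from water in ppm.
#' @slot fraction proton fraction relative to water (dimensionless, >= 0).
#' @slot R1 longitudinal relaxation rate, 1/s.
#' @slot R2 transverse relaxation rate, 1/s.
#' @slot kExch exchange rate pool -> water, 1/s.
#' @export
setClass("Pool",
  representation(
    name = "character",
    chemicalShift = "numeric",
    fraction = "numeric",
    R1 = "numeric",
    R2 = "numeric",
    kExch = "numeric"
  )
)

setValidity("Pool", function(object) {
  msg <- character()
  vals <- c(object@chemicalShift, object@fraction, object@R1, object@R2,
            object@kExch)
  if (!all(is.finite(vals))) msg <- c(msg, "all pool parameters must be finite")
  if (length(object@fraction) && object@fraction < 0)
    msg <- c(msg, "fraction must be >= 0")
  if (length(object@R1) && object@R1 <= 0) msg <- c(msg, "R1 must be > 0")
  if (length(object@R2) && object@R2 <= 0) msg <- c(msg, "R2 must be > 0")
  if (length(object@kExch) && object@kExch < 0)
    msg <- c(msg, "kExch must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a Pool
#'
#' @param name pool label.
#' @param chemicalShift ppm from water.
#' @param fraction proton fraction relative to water.
#' @param R1,R2 relaxation rates (1/s).
#' @param kExch exchange rate pool -> water (1/s).
#' @return A \linkS4class{Pool}.
#' @examples
#' Pool("amide", 3.5, 9e-4, 1, 30, 30)
#' @export
Pool <- function(name, chemicalShift, fraction, R1 = 1, R2 = 30, kExch = 0) {
  new("Pool", name = name, chemicalShift = as.numeric(chemicalShift),
      fraction = as.numeric(fraction), R1 = as.numeric(R1),
      R2 = as.numeric(R2), kExch = as.numeric(kExch))
}

#' Saturation offset schedule
#'
#' The saturation-offset list and pulse-train parameters defining one CEST
#' acquisition: a train of rectangular saturation pulses of duration
#' \code{tp} separated by gaps \code{td}, applied at each frequency offset.
#'
#' @slot offsets ordered saturation offsets, ppm from water.
#' @slot B1 saturation amplitude, microtesla.
#' @slot tp pulse duration, s.
#' @slot td inter-pulse spacing, s.
#' @slot nStartupPulses pulses applied before the steady-state readout train.
#' @slot nPulsesPerOffset saturation pulses per offset after startup.
#' @slot B0 static field, tesla.
#' @slot gamma gyromagnetic ratio, MHz/T.
#' @export
setClass("OffsetSchedule",
  representation(
    offsets = "numeric", B1 = "numeric", tp = "numeric", td = "numeric",
    nStartupPulses = "numeric", nPulsesPerOffset = "numeric",
    B0 = "numeric", gamma = "numeric"
  )
)

setValidity("OffsetSchedule", function(object) {
  msg <- character()
  if (!all(is.finite(object@offsets))) msg <- c(msg, "offsets must be finite")
  if (object@tp <= 0) msg <- c(msg, "tp must be > 0")
  if (object@td < 0) msg <- c(msg, "td must be >= 0")
  if (object@B1 < 0) msg <- c(msg, "B1 must be >= 0")
  if (object@B0 <= 0) msg <- c(msg, "B0 must be > 0")
  if (object@nStartupPulses < 0 || object@nPulsesPerOffset < 1)
    msg <- c(msg, "pulse counts invalid")
  if (length(msg)) msg else TRUE
})

#' Construct an OffsetSchedule
#'
#' @param offsets saturation offsets in ppm.
#' @param B1 saturation amplitude in microtesla.
#' @param tp,td pulse duration and spacing in seconds.
#' @param nStartupPulses,nPulsesPerOffset pulse-train counts.
#' @param B0 static field in tesla.
#' @param gamma gyromagnetic ratio in MHz/T.
#' @return An \linkS4class{OffsetSchedule}.
#' @seealso [schedulePreset()] for the built-in 3 T acquisition preset.
#' @export
offsetSchedule <- function(offsets, B1 = 1, tp = 0.25, td = 0.25,
                           nStartupPulses = 10, nPulsesPerOffset = 1,
                           B0 = 3, gamma = 42.577) {
  new("OffsetSchedule", offsets = as.numeric(offsets), B1 = as.numeric(B1),
      tp = as.numeric(tp), td = as.numeric(td),
      nStartupPulses = as.numeric(nStartupPulses),
      nPulsesPerOffset = as.numeric(nPulsesPerOffset),
      B0 = as.numeric(B0), gamma = as.numeric(gamma))
}

#' Tissue parameter set
#'
#' Water relaxation, the attached exchange pools and the intracellular pH of
#' one tissue class. The amide pool's exchange rate is driven from \code{pH}
#' through [amideExchangeRate()] when spectra are rendered.
#'
#' @slot waterR1 water longitudinal relaxation rate, 1/s (= 1/T1).
#' @slot waterR2 water transverse relaxation rate, 1/s.
#' @slot pools list of \linkS4class{Pool}.
#' @slot pH intracellular pH.
#' @export
setClass("TissueParams",
  representation(waterR1 = "numeric", waterR2 = "numeric",
                 pools = "list", pH = "numeric")
)

setValidity("TissueParams", function(object) {
  msg <- character()
  if (object@waterR1 <= 0 || object@waterR2 <= 0)
    msg <- c(msg, "water relaxation rates must be > 0")
  if (object@pH < 6 || object@pH > 8)
    msg <- c(msg, "pH outside supported range [6, 8]")
  if (length(object@pools) && !all(vapply(object@pools, is, TRUE, "Pool")))
    msg <- c(msg, "pools must be a list of Pool objects")
  if (length(msg)) msg else TRUE
})

#' Construct a TissueParams
#'
#' @param waterR1,waterR2 water relaxation rates (1/s).
#' @param pools list of \linkS4class{Pool} objects (may be empty for pure
#'   water).
#' @param pH intracellular pH in \[6, 8\].
#' @return A \linkS4class{TissueParams}.
#' @export
tissueParams <- function(waterR1, waterR2, pools = list(), pH = 7.0) {
  new("TissueParams", waterR1 = as.numeric(waterR1),
      waterR2 = as.numeric(waterR2), pools = pools, pH = as.numeric(pH))
}

#' Digital brain-tumor phantom
#'
#' Labelled 3D volume with per-class tissue parameters, a ground-truth pH
#' volume, a smooth delta-B0 field and a proton-density (M0) volume.
#' Label codes: 0 background, 1 WM, 2 GM, 3 CSF, 4 tumor rim,
#' 5 necrotic core.
#'
#' @slot labels integer 3D array of class labels.
#' @slot voxelSize voxel dimensions in mm (length 3).
#' @slot classParams named list label name -> \linkS4class{TissueParams}.
#' @slot classM0 named numeric, relative proton density per class.
#' @slot ph ground-truth pH volume (3D array).
#' @slot db0 delta-B0 field in ppm (3D array).
#' @slot m0 proton-density volume (3D array, arbitrary units).
#' @slot geometry the geometry configuration list used to build the phantom.
#' @slot seed integer seed the phantom was built with.
#' @export
setClass("DigitalPhantom",
  representation(labels = "array", voxelSize = "numeric",
                 classParams = "list", classM0 = "numeric",
                 ph = "array", db0 = "array", m0 = "array",
                 geometry = "list", seed = "numeric")
)

setValidity("DigitalPhantom", function(object) {
  msg <- character()
  if (any(object@voxelSize <= 0)) msg <- c(msg, "voxelSize must be > 0")
  inb <- object@labels > 0
  if (any(!is.finite(object@ph[inb])))
    msg <- c(msg, "ph must be defined wherever label != background")
  if (!identical(dim(object@labels), dim(object@ph)))
    msg <- c(msg, "labels and ph dimensions differ")
  if (length(msg)) msg else TRUE
})

#' Z-spectrum volume
#'
#' Normalized 4D CEST data: one Z value per offset per voxel, with the
#' offset axis canonicalized to strictly increasing ppm.
#'
#' @slot offsets ppm values, strictly increasing.
#' @slot z 4D array (x, y, z, offset) of normalized signal in \[0, 1\].
#' @slot voxelSize mm triple.
#' @slot mask logical 3D array of valid voxels.
#' @slot extrapolated logical 3D array flagging voxels whose edge offsets
#'   were filled by nearest-value extrapolation during B0 correction.
#' @export
setClass("ZSpectrumVolume",
  representation(offsets = "numeric", z = "array", voxelSize = "numeric",
                 mask = "array", extrapolated = "array")
)

setValidity("ZSpectrumVolume", function(object) {
  msg <- character()
  if (is.unsorted(object@offsets, strictly = TRUE))
    msg <- c(msg, "offsets must be strictly increasing")
  if (length(dim(object@z)) != 4L)
    msg <- c(msg, "z must be a 4D array")
  else if (dim(object@z)[4] != length(object@offsets))
    msg <- c(msg, "4th dimension of z must match offset count")
  if (any(!is.finite(object@z[.maskIdx4(object@mask, dim(object@z)[4])])))
    msg <- c(msg, "z must be finite inside the mask")
  if (length(msg)) msg else TRUE
})

# linear indices of all (voxel, offset) cells inside a 3D mask
.maskIdx4 <- function(mask, K) {
  n <- length(mask)
  idx <- which(mask)
  if (!length(idx)) return(integer())
  rep(idx, K) + rep((seq_len(K) - 1L) * n, each = length(idx))
}

#' CEST metric map
#'
#' A voxel map of one CEST metric (\code{MTR_asym}, \code{MTR_rex} or
#' \code{AREX}), possibly evaluated at several offsets (then \code{values}
#' is 4D with the offset axis last).
#'
#' @slot name metric name.
#' @slot deltaOmega evaluation offset(s), ppm.
#' @slot values 3D array (or 4D for an offset block); dimensionless for
#'   MTR metrics, 1/s for AREX.
#' @slot mask logical 3D array.
#' @slot voxelSize mm triple.
#' @export
setClass("MetricMap",
  representation(name = "character", deltaOmega = "numeric",
                 values = "array", mask = "array", voxelSize = "numeric")
)

setValidity("MetricMap", function(object) {
  d <- dim(object@values)
  v <- if (length(d) == 4L) {
    object@values[.maskIdx4(object@mask, d[4])]
  } else object@values[object@mask]
  if (any(!is.finite(v))) "values must be finite inside the mask" else TRUE
})

#' Probabilistic pH prediction map
#'
#' Predicted pH mean and 1-sigma uncertainty volumes, both in pH units.
#'
#' @slot phMean predicted pH (3D array; NA outside mask).
#' @slot phSigma predictive standard deviation in pH units (>= 0).
#' @slot mask logical 3D array.
#' @slot voxelSize mm triple.
#' @export
setClass("PredictionMap",
  representation(phMean = "array", phSigma = "array", mask = "array",
                 voxelSize = "numeric")
)

setValidity("PredictionMap", function(object) {
  msg <- character()
  s <- object@phSigma[object@mask]
  m <- object@phMean[object@mask]
  if (any(!is.finite(m)) || any(!is.finite(s)))
    msg <- c(msg, "mean/sigma must be finite inside the mask")
  if (any(s < 0)) msg <- c(msg, "sigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Trained probabilistic pH network
#'
#' A fully connected ReLU network with a probabilistic (mean + variance)
#' output head, together with the standardization statistics frozen from its
#' training split, its configuration and its training history.
#'
#' @slot weights list of layer weight matrices and bias vectors.
#' @slot config the [netConfig()] list used for training.
#' @slot stats standardization statistics (feature/target mean and sd).
#' @slot history per-epoch data.frame of train/validation losses and
#'   validation RMSE / Pearson r / R2 in destandardized pH units.
#' @slot featureDim expected input dimension.
#' @slot scheduleHash hash of the offset schedule the features came from.
#' @export
setClass("CestPhModel",
  representation(weights = "list", config = "list", stats = "list",
                 history = "data.frame", featureDim = "numeric",
                 scheduleHash = "character")
)

#' Paired synthetic acquisition
#'
#' One rendered dataset from a \linkS4class{DigitalPhantom}: raw 4D CEST +
#' M0 reference, delta-B0 map, quantitative T1 (and optionally the VFA GRE
#' pair), the coarse 31P pH target map, the eroded brain mask and the
#' ground-truth pH at CEST resolution.
#'
#' @slot cest4d raw CEST signal, 4D array (x, y, z, offset).
#' @slot m0 unsaturated reference volume.
#' @slot db0 delta-B0 map, ppm.
#' @slot qt1 quantitative T1 map, s.
#' @slot vfaPair list of two GRE magnitude volumes (empty unless rendered).
#' @slot ph31p list with elements \code{ph} (coarse 3D array, pH),
#'   \code{mask} (coarse logical array) and \code{voxelSize} (mm).
#' @slot mask eroded brain mask at CEST resolution (CSF excluded).
#' @slot truthPh ground-truth pH at CEST resolution.
#' @slot schedule the \linkS4class{OffsetSchedule} used for rendering.
#' @slot voxelSize CEST voxel size, mm.
#' @slot seed integer seed used for rendering.
#' @export
setClass("AcquiredDataset",
  representation(cest4d = "array", m0 = "array", db0 = "array",
                 qt1 = "array", vfaPair = "list", ph31p = "list",
                 mask = "array", truthPh = "array",
                 schedule = "OffsetSchedule", voxelSize = "numeric",
                 seed = "numeric")
)

setValidity("AcquiredDataset", function(object) {
  msg <- character()
  if (dim(object@cest4d)[4] != length(object@schedule@offsets))
    msg <- c(msg, "cest4d offset count must equal schedule length")
  if (!identical(dim(object@cest4d)[1:3], dim(object@m0)))
    msg <- c(msg, "cest4d and m0 grids differ")
  if (length(msg)) msg else TRUE
})
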