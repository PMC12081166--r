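#' Accessors for cestph objects
#'
#' Small accessor generics: \code{offsets()} returns the ppm offset axis,
#' \code{zValues()} the 4D Z-spectrum array, \code{voxelSize()} the voxel
#' dimensions in mm, \code{maskVolume()} the logical mask,
#' \code{metricValues()} a metric map's value array, \code{phMean()} /
#' \code{phSigma()} the prediction volumes, \code{phVolume()} a phantom's
#' ground-truth pH, \code{labelVolume()} its class labels, and
#' \code{trainingHistory()} a model's per-epoch metric log.
#'
#' @param x an object.
#' @return The corresponding slot value.
#' @name accessors
#' @aliases offsets zValues voxelSize maskVolume metricValues phMean phSigma
#'   phVolume labelVolume trainingHistory
NULL

#' @rdname accessors
#' @export
setGeneric("offsets", function(x) standardGeneric("offsets"))
#' @rdname accessors
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("maskVolume", function(x) standardGeneric("maskVolume"))
#' @rdname accessors
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))
#' @rdname accessors
#' @export
setGeneric("phMean", function(x) standardGeneric("phMean"))
#' @rdname accessors
#' @export
setGeneric("phSigma", function(x) standardGeneric("phSigma"))
#' @rdname accessors
#' @export
setGeneric("phVolume", function(x) standardGeneric("phVolume"))
#' @rdname accessors
#' @export
setGeneric("labelVolume", function(x) standardGeneric("labelVolume"))
#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname accessors
setMethod("offsets", "OffsetSchedule", function(x) x@offsets)
#' @rdname accessors
setMethod("offsets", "ZSpectrumVolume", function(x) x@offsets)
#' @rdname accessors
setMethod("zValues", "ZSpectrumVolume", function(x) x@z)
#' @rdname accessors
setMethod("voxelSize", "ZSpectrumVolume", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "DigitalPhantom", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "MetricMap", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "PredictionMap", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "AcquiredDataset", function(x) x@voxelSize)
#' @rdname accessors
setMethod("maskVolume", "ZSpectrumVolume", function(x) x@mask)
#' @rdname accessors
setMethod("maskVolume", "MetricMap", function(x) x@mask)
#' @rdname accessors
setMethod("maskVolume", "PredictionMap", function(x) x@mask)
#' @rdname accessors
setMethod("maskVolume", "AcquiredDataset", function(x) x@mask)
#' @rdname accessors
setMethod("metricValues", "MetricMap", function(x) x@values)
#' @rdname accessors
setMethod("phMean", "PredictionMap", function(x) x@phMean)
#' @rdname accessors
setMethod("phSigma", "PredictionMap", function(x) x@phSigma)
#' @rdname accessors
setMethod("phVolume", "DigitalPhantom", function(x) x@ph)
#' @rdname accessors
setMethod("labelVolume", "DigitalPhantom", function(x) x@labels)
#' @rdname accessors
setMethod("trainingHistory", "CestPhModel", function(x) x@history)

setMethod("show", "Pool", function(object) {
  cat(sprintf(
    "Pool '%s': %+.2f ppm, fraction %.2e, R1 %.3g /s, R2 %.3g /s, k %.3g /s\n",
    object@name, object@chemicalShift, object@fraction, object@R1,
    object@R2, object@kExch))
})

setMethod("show", "OffsetSchedule", function(object) {
  cat("OffsetSchedule:", length(object@offsets), "offsets in [",
      min(object@offsets), ",", max(object@offsets), "] ppm\n")
  cat(sprintf("  B1 = %.3g uT, tp = %.3g s, td = %.3g s, %d+%d pulses, B0 = %.3g T\n",
              object@B1, object@tp, object@td,
              as.integer(object@nStartupPulses),
              as.integer(object@nPulsesPerOffset), object@B0))
})

setMethod("show", "TissueParams", function(object) {
  cat(sprintf("TissueParams: T1 %.3g s, T2 %.3g s, pH %.2f, %d pool(s)\n",
              1 / object@waterR1, 1 / object@waterR2, object@pH,
              length(object@pools)))
  for (p in object@pools) show(p)
})

setMethod("show", "DigitalPhantom", function(object) {
  d <- dim(object@labels)
  tab <- table(factor(object@labels, levels = 0:5,
                      labels = c("background", "WM", "GM", "CSF",
                                 "tumor_rim", "necrotic_core")))
  cat(sprintf("DigitalPhantom %dx%dx%d, voxel %s mm, seed %d\n",
              d[1], d[2], d[3],
              paste(object@voxelSize, collapse = "x"),
              as.integer(object@seed)))
  print(tab)
})

setMethod("show", "ZSpectrumVolume", function(object) {
  d <- dim(object@z)
  cat(sprintf("ZSpectrumVolume %dx%dx%d, %d offsets [%g, %g] ppm, %d masked voxels\n",
              d[1], d[2], d[3], d[4], min(object@offsets),
              max(object@offsets), sum(object@mask)))
})

setMethod("show", "MetricMap", function(object) {
  cat(sprintf("MetricMap '%s' at %s ppm, %d masked voxels\n", object@name,
              paste(range(object@deltaOmega), collapse = ".."),
              sum(object@mask)))
})

setMethod("show", "PredictionMap", function(object) {
  m <- object@phMean[object@mask]
  s <- object@phSigma[object@mask]
  cat(sprintf("PredictionMap: %d voxels, pH %.3f +/- %.3f (mean of means +/- median sigma)\n",
              sum(object@mask), mean(m), stats::median(s)))
})

setMethod("show", "CestPhModel", function(object) {
  h <- object@history
  cat(sprintf("CestPhModel: %d features -> %s -> (mean, sigma), %d epochs\n",
              as.integer(object@featureDim),
              paste(object@config$hidden, collapse = "-"), nrow(h)))
  if (nrow(h))
    cat(sprintf("  final validation RMSE %.4f pH, r %.3f\n",
                h$valRmse[nrow(h)], h$valR[nrow(h)]))
})

setMethod("show", "AcquiredDataset", function(object) {
  d <- dim(object@cest4d)
  cat(sprintf("AcquiredDataset: CEST %dx%dx%dx%d (voxel %s mm), 31P grid %s, %d masked voxels\n",
              d[1], d[2], d[3], d[4],
              paste(object@voxelSize, collapse = "x"),
              paste(dim(object@ph31p$ph), collapse = "x"),
              sum(object@mask)))
})
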