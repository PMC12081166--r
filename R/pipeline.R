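#' Process a raw dataset into model inputs
#'
#' The post-processing chain applied to every dataset before training or
#' prediction: normalization by the unsaturated reference, WASSR-style B0
#' correction with the dataset's delta-B0 map, the APT-weighted MTRasym
#' block, and the (eroded) analysis mask.
#'
#' @param dataset an \linkS4class{AcquiredDataset} (or a list with the same
#'   elements, e.g. one read back from [writeDataset()] output).
#' @return list with \code{zvol} (B0-corrected
#'   \linkS4class{ZSpectrumVolume}), \code{asym} (the 11-point MTRasym
#'   block), \code{qt1} and \code{mask}.
#' @export
processDataset <- function(dataset) {
  zraw <- normalizeZ(dataset@cest4d, dataset@m0, dataset@schedule@offsets,
                     voxelSize = dataset@voxelSize, mask = dataset@mask)
  zcor <- b0Correct(zraw, dataset@db0)
  asym <- mtrAsymBlock(zcor)
  list(zvol = zcor, asym = asym, qt1 = dataset@qt1,
       mask = zcor@mask & dataset@mask)
}

#' Build the voxel-wise training table
#'
#' Assembles the feature matrix and pastes the low-resolution 31P pH map
#' onto the CEST grid (nearest-neighbour, mirroring the reslicing of
#' measured 31P maps) to give one pH target per masked voxel. Voxels whose
#' coarse target is missing are dropped.
#'
#' @param dataset an \linkS4class{AcquiredDataset}.
#' @param processed optional result of [processDataset()] (recomputed if
#'   missing).
#' @return list with \code{features}, \code{targets}, \code{voxels}
#'   (linear indices), \code{featureNames} and \code{processed}.
#' @export
trainingTable <- function(dataset, processed = NULL) {
  if (is.null(processed)) processed <- processDataset(dataset)
  ft <- assembleFeatures(processed$zvol, processed$asym, processed$qt1,
                         processed$mask)
  tgt <- upsampleNearest(dataset@ph31p$ph, dataset@ph31p$voxelSize,
                         dim(processed$mask), dataset@voxelSize)
  y <- tgt[ft$voxels]
  ok <- is.finite(y)
  list(features = ft$x[ok, , drop = FALSE], targets = y[ok],
       voxels = ft$voxels[ok], featureNames = ft$featureNames,
       processed = processed)
}

#' Save / load a model checkpoint
#'
#' Self-describing JSON archive holding the network weights, the training
#' configuration, the standardization statistics, the training history and
#' the schedule hash. Plain text; doubles survive to within one unit in
#' the last place.
#'
#' @param model a \linkS4class{CestPhModel}.
#' @param path checkpoint path (\code{.json}).
#' @return \code{readModelCheckpoint} returns the model; the writer returns
#'   \code{path} invisibly.
#' @name checkpoint
NULL

#' @rdname checkpoint
#' @export
writeModelCheckpoint <- function(model, path) {
  obj <- list(
    format = "cestph-checkpoint-1",
    featureDim = model@featureDim,
    scheduleHash = model@scheduleHash,
    config = model@config,
    stats = model@stats,
    weights = list(
      W = lapply(model@weights$W, function(w)
        list(dim = dim(w), values = as.numeric(w))),
      b = model@weights$b),
    history = as.list(model@history))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname checkpoint
#' @export
readModelCheckpoint <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(j$format, "cestph-checkpoint-1"))
    stop("not a cestph checkpoint: ", path)
  num <- function(x)
    vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v), 0)
  W <- lapply(j$weights$W, function(w)
    matrix(num(w$values), num(w$dim)[1], num(w$dim)[2]))
  b <- lapply(j$weights$b, num)
  cfg <- j$config
  cfg$hidden <- as.integer(num(cfg$hidden))
  new("CestPhModel",
      weights = list(W = W, b = b),
      config = cfg,
      stats = list(feature = list(mean = num(j$stats$feature$mean),
                                  sd = num(j$stats$feature$sd)),
                   target = list(mean = as.numeric(j$stats$target$mean),
                                 sd = as.numeric(j$stats$target$sd))),
      history = as.data.frame(lapply(j$history, num)),
      featureDim = as.numeric(j$featureDim),
      scheduleHash = as.character(j$scheduleHash))
}

#' Run the full synthetic end-to-end experiment
#'
#' The package's reference experiment: build the default digital tumor
#' phantom, render the paired dataset (CEST + M0 + delta-B0 + qT1 + coarse
#' 31P pH + mask), post-process, train the probabilistic network, and
#' evaluate the held-out split (RMSE, Pearson r, 1-sigma coverage), the
#' prediction map, the metric ladder against the low-resolution truth, and
#' the T1-attack on a matched healthy (tumor-free) phantom. All randomness
#' derives from \code{seed}.
#'
#' @param seed integer master seed.
#' @param epochs training epochs (the published recipe uses 1000; smaller
#'   values scale the experiment down for constrained runtimes).
#' @param geometry phantom geometry (default [phantomGeometry()]).
#' @param verbose print training progress.
#' @return list with \code{phantom}, \code{dataset}, \code{processed},
#'   \code{model}, \code{heldout} (rmse / r / coverage / n), \code{pred}
#'   (\linkS4class{PredictionMap}), \code{ladder} (data.frame),
#'   \code{attack} (list from [t1Attack()]) and \code{contrast}
#'   (predicted tumor-rim vs white-matter mean pH).
#' @export
runSyntheticExperiment <- function(seed = 1, epochs = 400,
                                   geometry = phantomGeometry(),
                                   verbose = FALSE) {
  seed <- as.integer(seed)
  phantom <- buildPhantom(geometry, seed = seed)
  dataset <- renderDataset(phantom, schedulePreset("paper_3T"), seed = seed)
  tt <- trainingTable(dataset)
  cfg <- netConfig(epochs = epochs, seed = seed)
  model <- trainDeepCest(tt$features, tt$targets, cfg, verbose = verbose)

  # held-out metrics on the same split the trainer used
  set.seed(cfg$seed)
  n <- nrow(tt$features)
  trainIdx <- sort(sample.int(n, floor(cfg$splitFraction * n)))
  valIdx <- setdiff(seq_len(n), trainIdx)
  pm <- .predictMatrix(model, tt$features[valIdx, , drop = FALSE])
  err <- pm[, "mean"] - tt$targets[valIdx]
  heldout <- list(rmse = sqrt(mean(err^2)),
                  r = stats::cor(pm[, "mean"], tt$targets[valIdx]),
                  coverage = mean(abs(err) <= pm[, "sigma"]),
                  n = length(valIdx))

  pr <- tt$processed
  pred <- predictPh(model, pr$zvol, pr$asym, pr$qt1, pr$mask)
  lab <- phantom@labels
  contrast <- c(WM = mean(pred@phMean[lab == 1L & pred@mask]),
                tumor_rim = mean(pred@phMean[lab == 4L & pred@mask]))

  maskNA <- function(m) { v <- m@values; v[!m@mask] <- NA; v }
  rex <- suppressMessages(mtrRex(pr$zvol, 3.5))
  ladder <- metricLadder(
    pred@phMean,
    list(MTR_asym = maskNA(mtrAsym(pr$zvol, 3.5)),
         MTR_rex = maskNA(rex),
         AREX = maskNA(arex(rex, pr$qt1)),
         qT1 = pr$qt1),
    dataset@ph31p$ph, dataset@voxelSize, dataset@ph31p$voxelSize, pr$mask)

  # T1 attack on a healthy phantom: tumor-like T1 pasted into WM
  geoH <- geometry
  geoH$tumorRadius <- 0
  phantomH <- buildPhantom(geoH, seed = seed + 1L)
  datasetH <- renderDataset(phantomH, schedulePreset("paper_3T"),
                            seed = seed + 1L)
  prH <- processDataset(datasetH)
  roi <- .wmSphereRoi(phantomH, prH$mask, radius = 20)
  fakeT1 <- 1 / phantom@classParams$tumor_rim@waterR1
  attack <- t1Attack(model, prH$zvol, prH$asym, prH$qt1, prH$mask, roi,
                     fakeT1)

  list(phantom = phantom, dataset = dataset, processed = pr, model = model,
       heldout = heldout, pred = pred, ladder = ladder, attack = attack,
       contrast = contrast)
}

# spherical white-matter ROI for the attack experiment, offset from the
# brain center so it sits inside one hemisphere
.wmSphereRoi <- function(phantom, mask, radius = 20) {
  d <- dim(phantom@labels)
  vs <- phantom@voxelSize
  ctr <- (d / 2 + c(d[1] / 6, 0, 0)) * vs
  ijk <- which(phantom@labels == 1L & mask, arr.ind = TRUE)
  pos <- sweep(ijk, 2, vs, "*")
  dist <- sqrt(rowSums(sweep(pos, 2, ctr, "-")^2))
  roi <- array(FALSE, d)
  roi[ijk[dist <= radius, , drop = FALSE]] <- TRUE
  if (!any(roi))  # tiny grids: fall back to any interior WM voxels
    roi[ijk[seq_len(min(20, nrow(ijk))), , drop = FALSE]] <- TRUE
  roi
}
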