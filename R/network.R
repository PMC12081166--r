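#' Network training configuration
#'
#' Defaults follow the published training recipe: three hidden ReLU layers
#' of 10, 20 and 10 neurons, a probabilistic output head (mean + variance),
#' Gaussian negative log-likelihood loss, Adam with learning rate 0.001,
#' batch size 256, 1000 epochs, 80/20 voxel-wise split. The larger
#' 64-128-256-512 architecture that was found to overfit can be reproduced
#' via \code{hidden = c(64, 128, 256, 512)}.
#'
#' @param hidden hidden layer sizes.
#' @param lr Adam learning rate.
#' @param batchSize minibatch size.
#' @param epochs training epochs (no early stopping by default).
#' @param splitFraction fraction of voxels used for training.
#' @param seed integer seed controlling split, initialization and shuffling.
#' @param varianceFloor lower clamp on the predicted variance
#'   (standardized units).
#' @param checkpointBest keep the weights of the best-validation epoch
#'   instead of the last (opt-in; default trains the fixed epoch count).
#' @return Configuration list.
#' @export
netConfig <- function(hidden = c(10, 20, 10), lr = 0.001, batchSize = 256,
                      epochs = 1000, splitFraction = 0.8, seed = 1,
                      varianceFloor = 1e-6, checkpointBest = FALSE) {
  stopifnot(all(hidden > 0), splitFraction > 0, splitFraction < 1,
            lr > 0, batchSize >= 1, epochs >= 1, varianceFloor > 0)
  list(hidden = as.integer(hidden), lr = lr,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       splitFraction = splitFraction, seed = as.integer(seed),
       varianceFloor = varianceFloor, checkpointBest = checkpointBest)
}

#' Gaussian negative log-likelihood loss
#'
#' Heteroscedastic regression loss (constant term dropped):
#' \deqn{L = \frac{1}{n}\sum_i \frac{1}{2}\left(\log\sigma^2_i +
#'       \frac{(y_i - \mu_i)^2}{\sigma^2_i}\right)}
#' Variances below \code{varianceFloor} are clamped to the floor.
#'
#' @param mu predicted means.
#' @param sigma2 predicted variances.
#' @param y targets.
#' @param varianceFloor lower clamp on \code{sigma2}.
#' @return Scalar loss (may be negative: the constant is dropped).
#' @examples
#' gnllLoss(1, 1, 1)  # 0 by the convention used here
#' @export
gnllLoss <- function(mu, sigma2, y, varianceFloor = 1e-6) {
  s2 <- pmax(sigma2, varianceFloor)
  mean(0.5 * (log(s2) + (y - mu)^2 / s2))
}

# numerically stable softplus and its derivative (sigmoid)
.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
.sigmoid <- function(x) 1 / (1 + exp(-x))

# He-style initialization of the fully connected stack; final layer has two
# heads: mean (linear) and a pre-softplus variance channel
.initWeights <- function(dIn, hidden) {
  sizes <- c(dIn, hidden, 2L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
    if (l == length(sizes) - 1L) {
      # start the variance head near softplus^-1(1): unit variance in
      # standardized units
      b[[l]][2] <- log(exp(1) - 1)
    }
  }
  list(W = W, b = b)
}

# forward pass; returns activations for backprop
.forward <- function(wts, X, varianceFloor) {
  L <- length(wts$W)
  A <- vector("list", L + 1L)
  A[[1]] <- X
  for (l in seq_len(L - 1L)) {
    Zl <- sweep(A[[l]] %*% wts$W[[l]], 2, wts$b[[l]], "+")
    A[[l + 1L]] <- pmax(Zl, 0)
  }
  out <- sweep(A[[L]] %*% wts$W[[L]], 2, wts$b[[L]], "+")
  mu <- out[, 1]
  s <- out[, 2]
  sigma2 <- .softplus(s) + varianceFloor
  list(A = A, s = s, mu = mu, sigma2 = sigma2)
}

# gradient of the mean-GNLL w.r.t. all weights for one batch
.backward <- function(wts, fw, y) {
  L <- length(wts$W)
  n <- length(y)
  r <- fw$mu - y
  dmu <- r / fw$sigma2 / n
  ds2 <- 0.5 * (1 / fw$sigma2 - r^2 / fw$sigma2^2) / n
  ds <- ds2 * .sigmoid(fw$s)
  dOut <- cbind(dmu, ds)
  dimnames(dOut) <- NULL
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- dOut
  for (l in L:1) {
    gW[[l]] <- crossprod(fw$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(wts$W[[l]])) * (fw$A[[l]] > 0)
    }
  }
  list(W = gW, b = gb)
}

#' Train the probabilistic pH network
#'
#' Voxel-wise heteroscedastic regression of standardized features onto
#' standardized pH targets with the fully connected ReLU network and GNLL
#' loss, optimized by Adam. The split is voxel-wise random (fixed seed),
#' standardization statistics are computed on the training split only and
#' frozen into the model, and the whole run is deterministic for a given
#' seed (fixed initialization and shuffling). Per epoch the train/
#' validation GNLL and the validation RMSE, Pearson r and R2 in
#' destandardized pH units are logged.
#'
#' @param features numeric matrix (voxels x features), raw scale.
#' @param targets numeric vector of pH targets, raw scale.
#' @param config a [netConfig()].
#' @param verbose print progress every 50 epochs.
#' @return A \linkS4class{CestPhModel}.
#' @export
trainDeepCest <- function(features, targets, config = netConfig(),
                          verbose = FALSE) {
  stopifnot(nrow(features) == length(targets), all(is.finite(targets)))
  set.seed(config$seed)
  n <- nrow(features)
  nTrain <- floor(config$splitFraction * n)
  trainIdx <- sort(sample.int(n, nTrain))
  valIdx <- setdiff(seq_len(n), trainIdx)

  sx <- standardizeFeatures(features[trainIdx, , drop = FALSE])
  sy <- standardizeFeatures(targets[trainIdx])
  Xtr <- sx$x
  ytr <- sy$x
  Xva <- standardizeFeatures(features[valIdx, , drop = FALSE], sx$stats)$x
  yvaRaw <- targets[valIdx]

  wts <- .initWeights(ncol(features), config$hidden)
  # Adam state
  mW <- lapply(wts$W, function(w) w * 0); vW <- mW
  mB <- lapply(wts$b, function(b) b * 0); vB <- mB
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  hist <- data.frame(epoch = seq_len(config$epochs), trainLoss = NA_real_,
                     valLoss = NA_real_, valRmse = NA_real_,
                     valR = NA_real_, valR2 = NA_real_)
  best <- list(loss = Inf, wts = wts)
  nb <- ceiling(nTrain / config$batchSize)

  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(nTrain)
    epLoss <- 0
    for (bi in seq_len(nb)) {
      rows <- perm[((bi - 1L) * config$batchSize + 1L):
                     min(bi * config$batchSize, nTrain)]
      fw <- .forward(wts, Xtr[rows, , drop = FALSE], config$varianceFloor)
      loss <- gnllLoss(fw$mu, fw$sigma2, ytr[rows], config$varianceFloor)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", ep,
             ", batch ", bi)
      epLoss <- epLoss + loss * length(rows)
      gr <- .backward(wts, fw, ytr[rows])
      step <- step + 1L
      bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
      for (l in seq_along(wts$W)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gr$W[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gr$W[[l]]^2
        wts$W[[l]] <- wts$W[[l]] -
          config$lr * (mW[[l]] / bc1) / (sqrt(vW[[l]] / bc2) + eps)
        mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gr$b[[l]]
        vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gr$b[[l]]^2
        wts$b[[l]] <- wts$b[[l]] -
          config$lr * (mB[[l]] / bc1) / (sqrt(vB[[l]] / bc2) + eps)
      }
    }
    fwv <- .forward(wts, Xva, config$varianceFloor)
    yvaStd <- (yvaRaw - sy$stats$mean) / sy$stats$sd
    valLoss <- gnllLoss(fwv$mu, fwv$sigma2, yvaStd, config$varianceFloor)
    pred <- .destandardize(fwv$mu, sy$stats)
    hist$trainLoss[ep] <- epLoss / nTrain
    hist$valLoss[ep] <- valLoss
    hist$valRmse[ep] <- sqrt(mean((pred - yvaRaw)^2))
    hist$valR[ep] <- suppressWarnings(stats::cor(pred, yvaRaw))
    hist$valR2[ep] <- hist$valR[ep]^2
    if (config$checkpointBest && valLoss < best$loss)
      best <- list(loss = valLoss, wts = wts)
    if (verbose && ep %% 50 == 0)
      message(sprintf("epoch %d: train %.4f val %.4f valRMSE %.4f",
                      ep, hist$trainLoss[ep], valLoss, hist$valRmse[ep]))
  }
  if (config$checkpointBest) wts <- best$wts

  new("CestPhModel", weights = wts, config = config,
      stats = list(feature = sx$stats,
                   target = list(mean = unname(sy$stats$mean),
                                 sd = unname(sy$stats$sd))),
      history = hist, featureDim = ncol(features),
      scheduleHash = NA_character_)
}

# raw-feature matrix -> destandardized (mean, sigma) matrix
.predictMatrix <- function(model, x) {
  if (ncol(x) != model@featureDim)
    stop("feature dimension mismatch: model expects ", model@featureDim,
         ", got ", ncol(x))
  xs <- standardizeFeatures(x, model@stats$feature)$x
  fw <- .forward(model@weights, xs, model@config$varianceFloor)
  ts <- model@stats$target
  cbind(mean = fw$mu * ts$sd + ts$mean,
        sigma = sqrt(fw$sigma2) * ts$sd)
}

#' Predict a pH map with uncertainty
#'
#' Runs the trained network voxel-wise over the masked feature rows and
#' returns destandardized predictive mean and standard deviation volumes.
#' The prediction is purely voxel-wise (no spatial coupling).
#'
#' @param model a trained \linkS4class{CestPhModel}.
#' @param zvol a B0-corrected \linkS4class{ZSpectrumVolume}.
#' @param asymBlock the [mtrAsymBlock()] map.
#' @param qt1 quantitative T1 map, s.
#' @param mask logical 3D array.
#' @return A \linkS4class{PredictionMap}.
#' @export
predictPh <- function(model, zvol, asymBlock, qt1, mask) {
  ft <- assembleFeatures(zvol, asymBlock, qt1, mask)
  pm <- .predictMatrix(model, ft$x)
  d <- dim(mask)
  mu <- array(NA_real_, d); sg <- array(NA_real_, d)
  mu[ft$voxels] <- pm[, "mean"]
  sg[ft$voxels] <- pm[, "sigma"]
  outMask <- array(FALSE, d); outMask[ft$voxels] <- TRUE
  new("PredictionMap", phMean = mu, phSigma = sg, mask = outMask,
      voxelSize = zvol@voxelSize)
}

#' T1-attack experiment
#'
#' Probes whether the prediction is driven by the CEST channels rather than
#' by T1: the quantitative T1 inside a region of interest is replaced by a
#' tumor-like fake value while the CEST channels are left untouched, the
#' model re-predicts, and the per-voxel pH changes are compared with the
#' predicted uncertainty. Outside the ROI the voxel-wise model is
#' unchanged by construction.
#'
#' @param model a trained \linkS4class{CestPhModel}.
#' @param zvol,asymBlock,qt1,mask prediction inputs as in [predictPh()].
#' @param roiMask logical 3D array, must lie inside \code{mask}.
#' @param fakeT1 replacement T1 inside the ROI, s.
#' @return list with \code{baseline} and \code{attacked}
#'   \linkS4class{PredictionMap}s, the \code{deltaMean} volume, and a
#'   \code{summary} data.frame (median and 90th percentile of |delta pH|
#'   inside/outside the ROI, and the median predicted sigma inside the
#'   ROI).
#' @export
t1Attack <- function(model, zvol, asymBlock, qt1, mask, roiMask, fakeT1) {
  roiMask <- as.logical(roiMask) & TRUE
  dim(roiMask) <- dim(mask)
  if (!any(roiMask)) stop("empty ROI")
  if (any(roiMask & !mask)) stop("ROI must lie inside the mask")
  base <- predictPh(model, zvol, asymBlock, qt1, mask)
  qt1a <- qt1
  qt1a[roiMask] <- fakeT1
  att <- predictPh(model, zvol, asymBlock, qt1a, mask)
  dM <- att@phMean - base@phMean
  inr <- roiMask & base@mask
  outr <- base@mask & !roiMask
  q90 <- function(x) unname(stats::quantile(abs(x), 0.9, na.rm = TRUE))
  summ <- data.frame(
    region = c("roi", "outside"),
    nVoxels = c(sum(inr), sum(outr)),
    medianAbsDelta = c(stats::median(abs(dM[inr])),
                       stats::median(abs(dM[outr]))),
    q90AbsDelta = c(q90(dM[inr]), q90(dM[outr])),
    medianSigma = c(stats::median(base@phSigma[inr]),
                    stats::median(base@phSigma[outr])))
  list(baseline = base, attacked = att, deltaMean = dM, summary = summ)
}
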