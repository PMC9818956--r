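# Two-stage training: unsupervised learning on unlabeled pairs, weight
# transfer, and semi-supervised fine-tuning on a small annotated set.

# Normalize a training record to list(fixed, moving, landmarks-or-NULL).
# The deformable stage always consumes pre-registered moving images, so a
# GroundTruthPair contributes its movingPrereg view.
asPairRecord <- function(p) {
  if (is(p, "GroundTruthPair"))
    return(list(fixed = p@fixed, moving = p@movingPrereg,
                landmarks = p@landmarks))
  if (is.list(p) && !is.null(p$fixed) && !is.null(p$moving))
    return(list(fixed = p$fixed, moving = p$moving,
                landmarks = p$landmarks))
  stop("each pair must be a GroundTruthPair or a list(fixed, moving[, landmarks])")
}

# Loss and parameter gradients for one image pair (landmarks optional).
pairLossGrad <- function(theta, config, rec, lambda, mu, similarity,
                         withLandmarks) {
  fw <- netForward(theta, config, rec$fixed, rec$moving, keepCache = TRUE)
  v <- fw$field
  warped <- warpImageDense(rec$moving, v)
  simVG <- similarityValueGrad(rec$fixed, warped, similarity)
  wb <- .warp_bilinear_bw(rec$moving, v[, , 1L], v[, , 2L], simVG$grad)
  dv <- array(c(wb$ddx, wb$ddy), dim(v))
  loss <- simVG$value
  if (lambda > 0) {
    loss <- loss + lambda * diffusionRegularizer(v, normalize = TRUE)
    dv <- dv + lambda * diffusionRegularizerGrad(v, normalize = TRUE)
  }
  if (withLandmarks) {
    lmk <- rec$landmarks
    k <- length(lmk)
    lm <- landmarkMapFirstOrder(v, lmk@movingPoints)
    e <- lm$mapped - lmk@fixedPoints
    loss <- loss + mu * mean(rowSums(e^2))
    if (mu > 0)
      dv <- dv + scatterPointGrad(v, lmk@movingPoints, -2 * mu / k * e)
  }
  grads <- netBackward(theta, config, fw$cache, dv)
  list(loss = loss, grads = grads)
}

adamInit <- function(theta) {
  list(m = lapply(theta, function(w) w * 0),
       v = lapply(theta, function(w) w * 0),
       t = 0L)
}

adamStep <- function(theta, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(theta)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    theta[[nm]] <- theta[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(theta = theta, state = state)
}

# Learning-rate schedule: constant until decayStartEpoch, then linear
# decay to zero at the final epoch.
lrAtEpoch <- function(cfg, epoch) {
  if (epoch < cfg@decayStartEpoch) return(cfg@learningRate)
  if (cfg@epochs == cfg@decayStartEpoch) return(0)
  cfg@learningRate *
    max(0, (cfg@epochs - epoch) / (cfg@epochs - cfg@decayStartEpoch))
}

trainLoop <- function(model, records, cfg, withLandmarks, phaseLabel) {
  if (!length(records)) stop("training dataset is empty")
  recs <- lapply(records, asPairRecord)
  if (withLandmarks) {
    missing <- which(vapply(recs, function(r) is.null(r$landmarks), logical(1L)))
    if (length(missing))
      stop(sprintf("record %d is missing landmark annotations", missing[1L]))
  }
  theta <- model@theta
  config <- model@config
  opt <- adamInit(theta)
  log <- data.frame(epoch = integer(), loss = numeric(), lr = numeric(),
                    phase = character())
  withSeed(cfg@seed, {
    n <- length(recs)
    for (epoch in seq_len(cfg@epochs)) {
      lr <- lrAtEpoch(cfg, epoch)
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg@batchSize)
      epochLoss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg@batchSize - 1L, n)]
        batchLoss <- 0
        batchGrads <- NULL
        for (i in idx) {
          lg <- pairLossGrad(theta, config, recs[[i]], cfg@lambda, cfg@mu,
                             cfg@similarity, withLandmarks)
          if (!is.finite(lg$loss))
            stop(sprintf(
              "non-finite loss (%g) at epoch %d, pair %d: aborting (check inputs and learning rate)",
              lg$loss, epoch, i))
          batchLoss <- batchLoss + lg$loss
          if (is.null(batchGrads)) batchGrads <- lg$grads
          else for (nm in names(batchGrads))
            batchGrads[[nm]] <- batchGrads[[nm]] + lg$grads[[nm]]
        }
        nb <- length(idx)
        for (nm in names(batchGrads))
          batchGrads[[nm]] <- batchGrads[[nm]] / nb
        if (lr > 0) {
          upd <- adamStep(theta, batchGrads, opt, lr)
          theta <- upd$theta; opt <- upd$state
        }
        epochLoss <- epochLoss + batchLoss
      }
      epochLoss <- epochLoss / n
      log <- rbind(log, data.frame(epoch = epoch, loss = epochLoss, lr = lr,
                                   phase = phaseLabel))
      if (cfg@verbose)
        message(sprintf("[%s] epoch %3d/%d  loss %.6f  lr %.2e",
                        phaseLabel, epoch, cfg@epochs, epochLoss, lr))
    }
  })
  new("RegistrationModel", config = config, theta = theta,
      trainingPhase = phaseLabel, history = rbind(model@history, log))
}

#' Unsupervised training of the displacement network
#'
#' Adam optimization of the unsupervised loss (similarity +
#' `lambda` x diffusion regularizer) over a stream of pre-registered,
#' preprocessed image pairs. The learning rate is constant until
#' `decayStartEpoch` and then decays linearly to zero at the final epoch;
#' batches are epoch-shuffled under `cfg@seed`, so a seeded run is
#' reproducible.
#'
#' @param model a [RegistrationModel] (untrained or resumable).
#' @param pairs list of [GroundTruthPair] objects or
#'   `list(fixed, moving)` records.
#' @param cfg a [TrainConfig].
#' @return the trained model (`trainingPhase = "unsupervised"`) with the
#'   per-epoch loss log appended to [trainingHistory()].
#' @export
trainUnsupervised <- function(model, pairs, cfg = deskTrainConfig()) {
  stopifnot(is(model, "RegistrationModel"), is(cfg, "TrainConfig"))
  validObject(cfg)
  trainLoop(model, pairs, cfg, withLandmarks = FALSE,
            phaseLabel = "unsupervised")
}

#' Transfer learned weights into a (possibly new) network
#'
#' Copies all convolutional parameters from `source` into a model built on
#' `targetCfg`. The two configurations must describe identical
#' convolutional topologies (the semi-supervised network shares the
#' unsupervised network's layers); a mismatch raises an error naming the
#' first differing layer. The copy can be verified with
#' [parameterChecksum()].
#'
#' @param source a trained [RegistrationModel].
#' @param targetCfg a [NetworkConfig] for the receiving network.
#' @return a [RegistrationModel] carrying the copied weights and the
#'   source's training phase (ready for fine-tuning).
#' @export
transferWeights <- function(source, targetCfg = NULL) {
  stopifnot(is(source, "RegistrationModel"))
  if (is.null(targetCfg)) targetCfg <- source@config
  stopifnot(is(targetCfg, "NetworkConfig"))
  validObject(targetCfg)
  want <- thetaShapes(targetCfg)
  have <- source@theta
  for (nm in names(want)) {
    shp <- want[[nm]]
    w <- have[[nm]]
    hshp <- if (is.matrix(w)) dim(w) else length(w)
    if (is.null(w) || !identical(as.integer(hshp), as.integer(shp)))
      stop(sprintf(
        "topology mismatch at layer '%s': target expects [%s], source has [%s]",
        nm, paste(shp, collapse = " x "),
        if (is.null(w)) "absent" else paste(hshp, collapse = " x ")))
  }
  new("RegistrationModel", config = targetCfg, theta = have[names(want)],
      trainingPhase = source@trainingPhase, history = source@history)
}

#' Semi-supervised fine-tuning on annotated pairs
#'
#' Continues training with the semi-supervised loss (unsupervised loss
#' plus `mu` x mean squared landmark distance) over a small set of
#' annotated pairs, updating all parameters (no freezing). The model may
#' be warm-started from unsupervised weights (the intended transfer
#' protocol) or fine-tuned from scratch (`"untrained"`) as an ablation.
#'
#' @param model a [RegistrationModel] with `trainingPhase` `"unsupervised"`
#'   or `"untrained"`.
#' @param annotated list of [GroundTruthPair] or
#'   `list(fixed, moving, landmarks)` records; every record must carry a
#'   [PairedLandmarks].
#' @param cfg a [TrainConfig]; `cfg@mu` weights the landmark term.
#' @return the fine-tuned model (`trainingPhase = "fine_tuned"`).
#' @export
fineTune <- function(model, annotated, cfg = deskTrainConfig()) {
  stopifnot(is(model, "RegistrationModel"), is(cfg, "TrainConfig"))
  validObject(cfg)
  if (!model@trainingPhase %in% c("unsupervised", "untrained"))
    stop(sprintf(
      "fine-tuning expects an 'unsupervised' (warm start) or 'untrained' (from scratch) model, got '%s'",
      model@trainingPhase))
  out <- trainLoop(model, annotated, cfg, withLandmarks = TRUE,
                   phaseLabel = "fine_tuned")
  out
}

#' Register a new image pair with a trained model
#'
#' One forward pass to predict the displacement field, followed by the
#' dense backward warp of the moving image -- a pure function of the
#' parameters and inputs.
#'
#' @param model a [RegistrationModel].
#' @param fixed,moving grayscale matrices matching the configured input
#'   size.
#' @return `list(field = DeformationField, warped = matrix)`.
#' @export
registerPair <- function(model, fixed, moving) {
  field <- predictField(model, fixed, moving)
  list(field = field, warped = warpImageDense(moving, field))
}

#' Save / load a model checkpoint
#'
#' Single-file archive of the architecture configuration, the full
#' parameter state, the training phase and the training history
#' (format version 1).
#'
#' @param model a [RegistrationModel].
#' @param path checkpoint file path.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "RegistrationModel"))
  cfg <- model@config
  saveRDS(list(
    format = "penreg-checkpoint", version = 1L,
    config = list(levels = cfg@levels, filtersPerLevel = cfg@filtersPerLevel,
                  kernelSize = cfg@kernelSize, activation = cfg@activation,
                  actSlope = cfg@actSlope,
                  useInstanceNorm = cfg@useInstanceNorm,
                  residualBlocks = cfg@residualBlocks,
                  inputSize = cfg@inputSize, fieldClamp = cfg@fieldClamp),
    theta = model@theta, trainingPhase = model@trainingPhase,
    history = model@history), path)
  invisible(path)
}

#' @rdname saveModel
#' @return `loadModel`: the restored [RegistrationModel] (lossless).
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "penreg-checkpoint"))
    stop("not a penreg checkpoint file")
  cfg <- do.call(NetworkConfig, x$config)
  new("RegistrationModel", config = cfg, theta = x$theta,
      trainingPhase = x$trainingPhase, history = x$history)
}
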