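# R-level surface of the compact convolutional classifier. The numerical
# engine (forward/backward, ADAM, dropout, batch norm, max-norm constraints)
# lives in src/eegnet.cpp; these wrappers own configuration, weight
# initialization, validation, and the conversion between EpochSet arrays and
# the engine's layout.

#' Network configuration
#'
#' @param F1 temporal filters (8 default; 4 is the alternative option).
#' @param D spatial filters per temporal filter (2).
#' @param temporalKernel,separableKernel kernel widths in samples.
#' @param pool1,pool2 average-pooling widths.
#' @param dropout dropout probability (0.25).
#' @param nClasses output classes (4).
#' @return A [NetConfig-class]; `F2` is set to `F1 * D`.
#' @export
#' @examples
#' netConfig(8, 2)
netConfig <- function(F1 = 8, D = 2, temporalKernel = 64, separableKernel = 16,
                      pool1 = 4, pool2 = 8, dropout = 0.25, nClasses = 4) {
  new("NetConfig", F1 = as.integer(F1), D = as.integer(D),
      F2 = as.integer(F1 * D), temporalKernel = as.integer(temporalKernel),
      separableKernel = as.integer(separableKernel),
      pool1 = as.integer(pool1), pool2 = as.integer(pool2),
      dropout = dropout, nClasses = as.integer(nClasses))
}

.cfgList <- function(cfg) {
  list(F1 = cfg@F1, D = cfg@D, F2 = cfg@F2,
       temporalKernel = cfg@temporalKernel,
       separableKernel = cfg@separableKernel,
       pool1 = cfg@pool1, pool2 = cfg@pool2,
       dropout = cfg@dropout, nClasses = cfg@nClasses)
}

.flatLength <- function(cfg, T) {
  cfg@F2 * ((T %/% cfg@pool1) %/% cfg@pool2)
}

# Glorot-uniform initialization, batch-norm scale 1 / shift 0
.initWeights <- function(cfg, C, T) {
  F1 <- cfg@F1; D <- cfg@D; F2 <- cfg@F2; N <- cfg@nClasses
  K1 <- cfg@temporalKernel; K2 <- cfg@separableKernel
  FL <- .flatLength(cfg, T)
  glorot <- function(nr, nc, fanIn, fanOut)
    matrix(runif(nr * nc, -1, 1) * sqrt(6 / (fanIn + fanOut)), nr, nc)
  list(W1 = glorot(F1, K1, K1, K1 * F1),
       Wd = glorot(F2, C, C, D),
       Wsd = glorot(F2, K2, K2, K2),
       Wsp = glorot(F2, F2, F2, F2),
       Wf = glorot(N, FL, FL, N), bf = numeric(N),
       g1 = rep(1, F1), b1 = numeric(F1),
       g2 = rep(1, F2), b2 = numeric(F2),
       g3 = rep(1, F2), b3 = numeric(F2),
       rm1 = numeric(F1), rv1 = rep(1, F1),
       rm2 = numeric(F2), rv2 = rep(1, F2),
       rm3 = numeric(F2), rv3 = rep(1, F2))
}

#' Build an (untrained) classifier for a given input geometry
#'
#' Block 1: temporal convolution (`F1` filters, width 64, same padding,
#' linear) -> batch norm -> depthwise spatial convolution spanning all
#' channels (`D` filters per temporal map) -> batch norm -> ELU -> average
#' pool 4 -> dropout. Block 2: separable convolution (depthwise width 16 +
#' pointwise) -> batch norm -> ELU -> average pool 8 -> dropout -> flatten ->
#' dense softmax. Convolutions carry no bias (each is followed by batch
#' norm); max-norm constraints of 1.0 (depthwise) and 0.25 (dense) are
#' enforced during training.
#'
#' @param config a [NetConfig-class].
#' @param channels channel names (or a channel count).
#' @param nTimepoints input length in samples (at least the temporal kernel).
#' @param seed seed for the weight initialization.
#' @return An untrained [TrainedModel-class].
#' @export
#' @examples
#' m <- buildModel(netConfig(4, 2), channels = 8, nTimepoints = 96)
#' nParameters(m)
buildModel <- function(config, channels, nTimepoints, seed = 1L) {
  stopifnot(is(config, "NetConfig"))
  if (is.numeric(channels) && length(channels) == 1)
    channels <- sprintf("ch%02d", seq_len(channels))
  C <- length(channels)
  T <- as.integer(nTimepoints)
  if (C < 2) stop("need at least 2 channels")
  if (T < config@temporalKernel)
    stop("nTimepoints must be at least the temporal kernel width (",
         config@temporalKernel, ")")
  if ((T %/% config@pool1) %/% config@pool2 < 1)
    stop("input too short: no timepoints left after pooling")
  set.seed(seed)
  w <- .initWeights(config, C, T)
  new("TrainedModel", config = config, channels = channels,
      nTimepoints = T, weights = w, finalWeights = w,
      history = data.frame(epoch = integer(), train_loss = numeric(),
                           val_loss = numeric()),
      bestEpoch = 0L, classLevels = character())
}

#' @rdname accessors
setMethod("nParameters", "TrainedModel", function(object) {
  cfg <- object@config
  C <- length(object@channels)
  FL <- .flatLength(cfg, object@nTimepoints)
  cfg@F1 * cfg@temporalKernel + 2L * cfg@F1 +          # temporal conv + BN
    C * cfg@D * cfg@F1 + 2L * cfg@F2 +                 # depthwise + BN
    cfg@separableKernel * cfg@F2 + cfg@F2 * cfg@F2 +   # separable (dw + pw)
    2L * cfg@F2 +                                      # BN
    FL * cfg@nClasses + cfg@nClasses                   # dense + bias
})

#' Inverse-proportion class weights
#'
#' Weight of class k is `max(counts) / counts[k]`: the inverse of the class
#' proportion, normalized so the majority class has weight exactly 1.
#'
#' @param counts positive per-class counts (optionally named).
#' @return Numeric weights, same order/names as `counts`.
#' @export
#' @examples
#' classWeights(c(100, 100, 100, 50))
classWeights <- function(counts) {
  if (any(counts <= 0)) stop("all class counts must be positive")
  max(counts) / counts
}

.epochArray <- function(epochs) {
  # EpochSet stores trials x channels x timepoints; the engine wants
  # channels x timepoints x trials
  aperm(epochs@data, c(2, 3, 1))
}

.checkGeometry <- function(model, epochs) {
  if (nChannels(epochs) != length(model@channels) ||
      nTimepoints(epochs) != model@nTimepoints)
    stop(sprintf(
      "epoch geometry (%d x %d) does not match the model (%d x %d)",
      nChannels(epochs), nTimepoints(epochs), length(model@channels),
      model@nTimepoints))
}

#' Train the classifier
#'
#' ADAM optimization (learning rate 1e-3, default moments) of the
#' class-weighted cross-entropy for up to `maxEpochs` epochs at the given
#' batch size. After every epoch the (unweighted) validation cross-entropy is
#' recorded; the returned weights are those of the epoch with the minimum
#' validation loss. Training is deterministic for a fixed seed.
#'
#' @param model an untrained or trained [TrainedModel-class].
#' @param train,val [EpochSet-class] objects with identical label sets.
#' @param maxEpochs maximum epochs (500 by default).
#' @param batchSize minibatch size (32).
#' @param lr ADAM learning rate.
#' @param seed seed for shuffling and dropout.
#' @return The trained model (checkpointed weights, history, `bestEpoch`).
#' @export
trainModel <- function(model, train, val, maxEpochs = 500, batchSize = 32,
                       lr = 1e-3, seed = 1L) {
  stopifnot(is(model, "TrainedModel"), is(train, "EpochSet"),
            is(val, "EpochSet"))
  .checkGeometry(model, train); .checkGeometry(model, val)
  if (nTrials(val) == 0) stop("validation set is empty")
  lv <- levels(train@labels)
  if (!identical(lv, levels(val@labels)))
    stop("train and validation label sets differ")
  counts <- table(train@labels)
  if (any(counts == 0))
    stop("class missing from the training set: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  if (length(lv) != model@config@nClasses)
    stop("label set size does not match the model's class count")
  cw <- classWeights(as.numeric(counts))
  fit <- cppNetTrain(.epochArray(train),
                     as.integer(train@labels) - 1L,
                     .epochArray(val),
                     as.integer(val@labels) - 1L,
                     model@weights, .cfgList(model@config), cw,
                     as.integer(maxEpochs), as.integer(batchSize), lr,
                     as.integer(seed))
  model@weights <- fit$weights
  model@finalWeights <- fit$finalWeights
  model@history <- data.frame(epoch = seq_len(maxEpochs),
                              train_loss = fit$trainLoss,
                              val_loss = fit$valLoss)
  model@bestEpoch <- as.integer(fit$bestEpoch)
  model@classLevels <- lv
  model
}

#' Predict class probabilities and pre-softmax scores
#'
#' Inference uses the checkpointed weights with dropout disabled and running
#' batch-norm statistics, so repeated calls are identical. The pre-softmax
#' scores are the quantities differentiated for saliency maps.
#'
#' @param model a trained [TrainedModel-class].
#' @param epochs an [EpochSet-class] matching the model geometry.
#' @return List with `probabilities` (trials x classes, rows sum to 1),
#'   `scores` (pre-softmax), and `predicted` (factor).
#' @export
predictModel <- function(model, epochs) {
  stopifnot(is(model, "TrainedModel"), is(epochs, "EpochSet"))
  .checkGeometry(model, epochs)
  out <- cppNetPredict(.epochArray(epochs), model@weights,
                       .cfgList(model@config))
  lv <- if (length(model@classLevels)) model@classLevels
        else as.character(seq_len(model@config@nClasses))
  colnames(out$probabilities) <- lv
  colnames(out$scores) <- lv
  pred <- factor(lv[max.col(out$probabilities, ties.method = "first")],
                 levels = lv)
  list(probabilities = out$probabilities, scores = out$scores,
       predicted = pred)
}

#' Choose between candidate filter configurations
#'
#' Runs the full leave-one-subject-out evaluation for each candidate
#' `(F1, D)` pair and returns the configuration with the higher mean
#' accuracy; ties go to the larger `F1`.
#'
#' @param epochsList named list of per-subject [EpochSet-class] objects.
#' @param candidates list of `c(F1, D)` pairs.
#' @param ... passed to [runLoos()].
#' @return List with `config` (the winning [NetConfig-class]) and
#'   `meanAccuracy` (named vector, one entry per candidate).
#' @export
selectFilterConfig <- function(epochsList,
                               candidates = list(c(4, 2), c(8, 2)), ...) {
  if (length(candidates) < 1) stop("need at least one candidate")
  accs <- numeric(length(candidates))
  names(accs) <- vapply(candidates, function(p)
    sprintf("(%d,%d)", p[1], p[2]), "")
  for (i in seq_along(candidates)) {
    cfg <- netConfig(F1 = candidates[[i]][1], D = candidates[[i]][2])
    res <- runLoos(epochsList, cfg, ...)
    accs[i] <- res$summary$meanAccuracy
  }
  best <- which(accs == max(accs))
  if (length(best) > 1)
    best <- best[which.max(vapply(candidates[best], `[`, 0, 1))]
  list(config = netConfig(F1 = candidates[[best]][1],
                          D = candidates[[best]][2]),
       meanAccuracy = accs)
}
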