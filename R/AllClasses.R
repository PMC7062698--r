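# S4 containers for the pipeline: electrode geometry, continuous recordings,
# stimulus-locked epochs, network configuration and trained models.

#' The four Simon-task trial classes
#'
#' Fixed enumeration of the hand-by-conflict design, in the conventional
#' order: left-hand non-conflict, left-hand conflict, right-hand
#' non-conflict, right-hand conflict.
#'
#' @return Character vector of the four class labels.
#' @export
#' @examples
#' trialClasses()
trialClasses <- function() {
  c("left_nonconflict", "left_conflict", "right_nonconflict", "right_conflict")
}

#' Side of the target stimulus implied by hand and conflict
#'
#' In the Simon task the stimulus appears on the same side as the responding
#' hand on non-conflict trials and on the opposite side on conflict trials;
#' stimulus side is therefore a pure function of (hand, conflict).
#'
#' @param hand "left" or "right" (vectorised).
#' @param conflict "conflict" or "nonconflict" (vectorised).
#' @return Character vector, "left" or "right".
#' @export
#' @examples
#' stimulusSide("left", "conflict")   # stimulus on the right
stimulusSide <- function(hand, conflict) {
  stopifnot(all(hand %in% c("left", "right")),
            all(conflict %in% c("conflict", "nonconflict")))
  ifelse(conflict == "nonconflict", hand,
         ifelse(hand == "left", "right", "left"))
}

#' Compose a trial-class label from hand and conflict
#' @param hand "left" or "right".
#' @param conflict "conflict" or "nonconflict".
#' @return Factor with the levels of [trialClasses()].
#' @export
trialClassLabel <- function(hand, conflict) {
  lab <- paste0(hand, "_", conflict)
  factor(lab, levels = trialClasses())
}

#' Electrode montage
#'
#' Channel names with unit-sphere sensor positions; the geometric substrate
#' for the spherical-spline current source density transform and for the
#' spatial mixing of simulated background activity.
#'
#' @slot channels character vector of unique channel names.
#' @slot positions numeric matrix (channels x 3) of unit-norm positions,
#'   row names matching `channels`.
#' @export
setClass("Montage",
         slots = c(channels = "character", positions = "matrix"))

setValidity("Montage", function(object) {
  p <- object@positions
  if (length(object@channels) != nrow(p))
    return("positions must have one row per channel")
  if (anyDuplicated(object@channels))
    return("channel names must be unique")
  nrm <- sqrt(rowSums(p^2))
  if (any(abs(nrm - 1) > 1e-9))
    return("all positions must have unit norm (within 1e-9)")
  TRUE
})

#' Continuous EEG recording with event markers
#'
#' @slot subjectId subject label.
#' @slot sfreq sampling rate in Hz.
#' @slot data channels x samples matrix, microvolts.
#' @slot events data.frame with columns `onset_sample`, `hand`, `conflict`,
#'   `correct`, `rt_ms`; onsets strictly increasing.
#' @slot montage a [Montage-class].
#' @slot metadata free-form list (simulation ground truth lives here).
#' @export
setClass("ContinuousRecording",
         slots = c(subjectId = "character", sfreq = "numeric",
                   data = "matrix", events = "data.frame",
                   montage = "Montage", metadata = "list"))

setValidity("ContinuousRecording", function(object) {
  if (nrow(object@data) != length(object@montage@channels))
    return("data row count must match montage channel count")
  if (!all(is.finite(object@data)))
    return("data must be finite")
  ev <- object@events
  need <- c("onset_sample", "hand", "conflict", "correct", "rt_ms")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  if (nrow(ev) > 1 && any(diff(ev$onset_sample) <= 0))
    return("event onsets must be strictly increasing")
  if (any(!is.na(ev$rt_ms) & ev$rt_ms <= 0))
    return("rt_ms must be positive when present")
  TRUE
})

#' Stimulus-locked single-trial epochs
#'
#' @slot subjectId subject label.
#' @slot sfreq sampling rate in Hz.
#' @slot data trials x channels x timepoints array (microvolts, or
#'   microvolts/cm^2 once `csdApplied`).
#' @slot timeMs time axis in ms relative to stimulus onset.
#' @slot labels factor of trial classes, one per trial.
#' @slot montage a [Montage-class].
#' @slot csdApplied logical, whether the current source density transform has
#'   been applied.
#' @slot metadata free-form list.
#' @export
setClass("EpochSet",
         slots = c(subjectId = "character", sfreq = "numeric", data = "array",
                   timeMs = "numeric", labels = "factor", montage = "Montage",
                   csdApplied = "logical", metadata = "list"))

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  if (length(d) != 3)
    return("data must be a trials x channels x timepoints array")
  if (d[1] != length(object@labels))
    return("labels length must equal the trial count")
  if (d[2] != length(object@montage@channels))
    return("channel dimension must match the montage")
  if (d[3] != length(object@timeMs))
    return("time axis length must match the timepoint dimension")
  if (length(object@timeMs) > 1) {
    dt <- diff(object@timeMs)
    if (max(abs(dt - 1000 / object@sfreq)) > 1e-6)
      return("time axis must be uniform at 1000/sfreq ms steps")
  }
  if (!all(is.finite(object@data)))
    return("data must be finite")
  TRUE
})

#' Network configuration for the compact convolutional classifier
#'
#' `F2` is tied to `F1 * D`. The defaults are the (8, 2) temporal/spatial
#' filter option; (4, 2) is the selectable alternative.
#'
#' @slot F1 number of temporal filters.
#' @slot D spatial (depthwise) filters per temporal filter.
#' @slot F2 separable-convolution filters, equal to `F1 * D`.
#' @slot temporalKernel temporal kernel width in samples (64).
#' @slot separableKernel separable kernel width in samples (16).
#' @slot pool1,pool2 average-pooling widths of blocks 1 and 2.
#' @slot dropout dropout probability.
#' @slot nClasses number of output classes.
#' @export
setClass("NetConfig",
         slots = c(F1 = "integer", D = "integer", F2 = "integer",
                   temporalKernel = "integer", separableKernel = "integer",
                   pool1 = "integer", pool2 = "integer", dropout = "numeric",
                   nClasses = "integer"))

setValidity("NetConfig", function(object) {
  if (object@F2 != object@F1 * object@D)
    return("F2 must equal F1 * D")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must be in [0, 1)")
  if (object@nClasses < 2) return("nClasses must be at least 2")
  TRUE
})

#' A (possibly trained) convolutional classifier
#'
#' Holds the layer weights, the per-epoch training/validation cross-entropy
#' history and the index of the checkpointed epoch (the one with the lowest
#' validation loss, whose weights are stored in `weights`).
#'
#' @slot config a [NetConfig-class].
#' @slot channels channel names the model was built for.
#' @slot nTimepoints input length in samples.
#' @slot weights named list of layer parameters (best checkpoint).
#' @slot finalWeights weights after the last epoch.
#' @slot history data.frame with columns `epoch`, `train_loss`, `val_loss`.
#' @slot bestEpoch integer index of the checkpointed epoch (0 if untrained).
#' @slot classLevels class labels in output order.
#' @export
setClass("TrainedModel",
         slots = c(config = "NetConfig", channels = "character",
                   nTimepoints = "integer", weights = "list",
                   finalWeights = "list", history = "data.frame",
                   bestEpoch = "integer", classLevels = "character"))

setValidity("TrainedModel", function(object) {
  h <- object@history
  if (nrow(h) > 0) {
    if (object@bestEpoch < 1 || object@bestEpoch > nrow(h))
      return("bestEpoch must index a row of the history")
    if (abs(h$val_loss[object@bestEpoch] - min(h$val_loss)) > 1e-9)
      return("checkpointed epoch must attain the minimum validation loss")
  }
  TRUE
})

#' Simulation configuration for synthetic Simon-task cohorts
#'
#' Defaults reproduce the task structure (400 trials, response-stimulus
#' interval 2000-2500 ms, 500 Hz, 60 channels) and the reported behavioral
#' means (correct RT 393/430 ms and error rates 3.4%/9.6% for
#' non-conflict/conflict). Component amplitudes are free parameters of the
#' generator: the planted parieto-occipital N1-like lateralization
#' (190-250 ms), the fronto-central conflict negativity (300-400 ms) and the
#' hand-lateralized motor component preceding the response.
#'
#' @slot nTrials trials per subject.
#' @slot rsiRangeMs response-stimulus interval range, ms.
#' @slot n1AmplitudeUv,conflictAmplitudeUv,motorAmplitudeUv peak component
#'   amplitudes, microvolts.
#' @slot n1WindowMs,conflictWindowMs component windows, ms post-stimulus.
#' @slot noiseScaleUv standard deviation of the 1/f background, microvolts.
#' @slot rtNonconflictMs,rtConflictMs mean correct RT per conflict condition.
#' @slot errNonconflict,errConflict error rates per conflict condition.
#' @slot sfreq sampling rate, Hz.
#' @slot nChannels montage size.
#' @slot seed master seed.
#' @export
setClass("SimulationConfig",
         slots = c(nTrials = "integer", rsiRangeMs = "numeric",
                   n1AmplitudeUv = "numeric", n1WindowMs = "numeric",
                   conflictAmplitudeUv = "numeric", conflictWindowMs = "numeric",
                   motorAmplitudeUv = "numeric", noiseScaleUv = "numeric",
                   rtNonconflictMs = "numeric", rtConflictMs = "numeric",
                   errNonconflict = "numeric", errConflict = "numeric",
                   sfreq = "numeric", nChannels = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nTrials < 4) return("nTrials must be at least 4")
  if (any(c(object@n1AmplitudeUv, object@conflictAmplitudeUv,
            object@motorAmplitudeUv, object@noiseScaleUv) < 0))
    return("amplitudes must be non-negative")
  if (any(c(object@errNonconflict, object@errConflict) < 0) ||
      any(c(object@errNonconflict, object@errConflict) > 1))
    return("error rates must be in [0, 1]")
  for (w in list(object@n1WindowMs, object@conflictWindowMs)) {
    if (length(w) != 2 || w[1] >= w[2] || w[1] <= 0 || w[2] >= 1500)
      return("component windows must be increasing and inside (0, 1500) ms")
  }
  if (diff(object@rsiRangeMs) < 0) return("rsiRangeMs must be increasing")
  TRUE
})

#' Class-averaged saliency map
#'
#' @slot classLabel the trial class the map belongs to.
#' @slot map channels x timepoints matrix, min-max normalized to [0, 1].
#' @slot nTrials number of trials averaged.
#' @slot timeMs time axis in ms.
#' @export
setClass("SaliencyMap",
         slots = c(classLabel = "character", map = "matrix",
                   nTrials = "integer", timeMs = "numeric"))

setValidity("SaliencyMap", function(object) {
  if (ncol(object@map) != length(object@timeMs))
    return("map columns must match the time axis")
  rng <- range(object@map)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    return("map values must lie in [0, 1]")
  TRUE
})
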