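# Accessor generics and show methods.

#' @rdname accessors
#' @param object an eegconflict object.
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("channelPositions", function(object) standardGeneric("channelPositions"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("nTimepoints", function(object) standardGeneric("nTimepoints"))
#' @rdname accessors
#' @export
setGeneric("epochData", function(object) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("epochLabels", function(object) standardGeneric("epochLabels"))
#' @rdname accessors
#' @export
setGeneric("epochTimes", function(object) standardGeneric("epochTimes"))
#' @rdname accessors
#' @export
setGeneric("getMontage", function(object) standardGeneric("getMontage"))
#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(object) standardGeneric("trainingHistory"))
#' @rdname accessors
#' @export
setGeneric("bestEpoch", function(object) standardGeneric("bestEpoch"))
#' @rdname accessors
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))
#' @rdname accessors
#' @export
setGeneric("nParameters", function(object) standardGeneric("nParameters"))

#' Accessors for eegconflict objects
#'
#' Small read-only accessors: subject label, sampling rate, channel
#' names/positions, epoch array and labels, training history and so on.
#'
#' @name accessors
#' @aliases subjectId samplingRate channelNames channelPositions nTrials
#'   nChannels nTimepoints epochData epochLabels epochTimes getMontage
#'   trainingHistory bestEpoch modelConfig nParameters
NULL

#' @rdname accessors
setMethod("channelNames", "Montage", function(object) object@channels)
#' @rdname accessors
setMethod("channelPositions", "Montage", function(object) object@positions)
#' @rdname accessors
setMethod("nChannels", "Montage", function(object) length(object@channels))

#' @rdname accessors
setMethod("subjectId", "ContinuousRecording", function(object) object@subjectId)
#' @rdname accessors
setMethod("samplingRate", "ContinuousRecording", function(object) object@sfreq)
#' @rdname accessors
setMethod("channelNames", "ContinuousRecording",
          function(object) object@montage@channels)
#' @rdname accessors
setMethod("nChannels", "ContinuousRecording", function(object) nrow(object@data))
#' @rdname accessors
setMethod("getMontage", "ContinuousRecording", function(object) object@montage)

#' @rdname accessors
setMethod("subjectId", "EpochSet", function(object) object@subjectId)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(object) object@sfreq)
#' @rdname accessors
setMethod("channelNames", "EpochSet", function(object) object@montage@channels)
#' @rdname accessors
setMethod("nTrials", "EpochSet", function(object) dim(object@data)[1])
#' @rdname accessors
setMethod("nChannels", "EpochSet", function(object) dim(object@data)[2])
#' @rdname accessors
setMethod("nTimepoints", "EpochSet", function(object) dim(object@data)[3])
#' @rdname accessors
setMethod("epochData", "EpochSet", function(object) object@data)
#' @rdname accessors
setMethod("epochLabels", "EpochSet", function(object) object@labels)
#' @rdname accessors
setMethod("epochTimes", "EpochSet", function(object) object@timeMs)
#' @rdname accessors
setMethod("getMontage", "EpochSet", function(object) object@montage)

#' @rdname accessors
setMethod("trainingHistory", "TrainedModel", function(object) object@history)
#' @rdname accessors
setMethod("bestEpoch", "TrainedModel", function(object) object@bestEpoch)
#' @rdname accessors
setMethod("modelConfig", "TrainedModel", function(object) object@config)
#' @rdname accessors
setMethod("nTimepoints", "TrainedModel", function(object) object@nTimepoints)
#' @rdname accessors
setMethod("channelNames", "TrainedModel", function(object) object@channels)

setMethod("show", "Montage", function(object) {
  cat(sprintf("Montage with %d channels: %s ...\n", nChannels(object),
              paste(head(object@channels, 6), collapse = ", ")))
})

setMethod("show", "ContinuousRecording", function(object) {
  cat(sprintf(
    "ContinuousRecording '%s': %d channels x %d samples @ %g Hz, %d events\n",
    object@subjectId, nrow(object@data), ncol(object@data), object@sfreq,
    nrow(object@events)))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochSet '%s': %d trials x %d channels x %d timepoints @ %g Hz%s\n",
    object@subjectId, d[1], d[2], d[3], object@sfreq,
    if (object@csdApplied) " (CSD)" else ""))
  print(table(object@labels))
})

setMethod("show", "NetConfig", function(object) {
  cat(sprintf(
    "NetConfig: F1=%d, D=%d, F2=%d; kernels %d/%d, pools %d/%d, dropout %.2f, %d classes\n",
    object@F1, object@D, object@F2, object@temporalKernel,
    object@separableKernel, object@pool1, object@pool2, object@dropout,
    object@nClasses))
})

setMethod("show", "TrainedModel", function(object) {
  trained <- nrow(object@history) > 0
  cat(sprintf(
    "TrainedModel (F1=%d, D=%d) for %d channels x %d timepoints: %s\n",
    object@config@F1, object@config@D, length(object@channels),
    object@nTimepoints,
    if (trained)
      sprintf("trained %d epochs, checkpoint at epoch %d (val loss %.4f)",
              nrow(object@history), object@bestEpoch,
              object@history$val_loss[object@bestEpoch])
    else "untrained"))
})

setMethod("show", "SaliencyMap", function(object) {
  cat(sprintf(
    "SaliencyMap for class '%s': %d channels x %d timepoints (n=%d trials)\n",
    object@classLabel, nrow(object@map), ncol(object@map), object@nTrials))
})
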