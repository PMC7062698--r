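# Gradient saliency: |d score_class / d input| per trial, class-averaged and
# min-max normalized. The gradient is taken with respect to the pre-softmax
# classification score, in inference mode (dropout off, running batch-norm
# statistics), so the map reflects the deployed classifier.

#' Single-trial saliency map
#'
#' Elementwise absolute gradient of the pre-softmax score of `classIndex`
#' with respect to the input trial.
#'
#' @param model a trained [TrainedModel-class].
#' @param trial channels x timepoints matrix matching the model geometry.
#' @param classIndex class index in 1..nClasses (or a class label).
#' @return channels x timepoints matrix of gradient magnitudes.
#' @export
trialSaliency <- function(model, trial, classIndex) {
  stopifnot(is(model, "TrainedModel"), is.matrix(trial))
  if (nrow(trial) != length(model@channels) ||
      ncol(trial) != model@nTimepoints)
    stop("trial shape does not match the model")
  if (is.character(classIndex))
    classIndex <- match(classIndex, model@classLevels)
  if (is.na(classIndex) || classIndex < 1 ||
      classIndex > model@config@nClasses)
    stop("classIndex out of range")
  x <- array(trial, dim = c(dim(trial), 1))
  g <- cppNetInputGrad(x, model@weights, .cfgList(model@config),
                       as.integer(classIndex) - 1L)
  out <- abs(g[, , 1])
  rownames(out) <- model@channels
  out
}

#' Class-averaged, normalized saliency map
#'
#' Per-trial gradient maps of the trials' own (true) class score are
#' rectified (absolute value, the default) and averaged; the averaged map is
#' then min-max normalized so its minimum is 0 and its maximum 1. With
#' `rectify = FALSE` signed gradients are averaged first and the absolute
#' value of the mean is normalized instead.
#'
#' @param model a trained [TrainedModel-class].
#' @param epochs an [EpochSet-class] matching the model geometry.
#' @param classLabel one of the label levels present in `epochs`.
#' @param rectify average |gradient| (default) rather than signed gradients.
#' @return A [SaliencyMap-class].
#' @export
classAverageSaliency <- function(model, epochs, classLabel, rectify = TRUE) {
  stopifnot(is(model, "TrainedModel"), is(epochs, "EpochSet"))
  .checkGeometry(model, epochs)
  idx <- which(as.character(epochLabels(epochs)) == classLabel)
  if (!length(idx)) stop("no trials with class '", classLabel, "'")
  k <- match(classLabel, model@classLevels)
  if (is.na(k)) stop("model was not trained on class '", classLabel, "'")
  x <- .epochArray(epochs)[, , idx, drop = FALSE]
  g <- cppNetInputGrad(x, model@weights, .cfgList(model@config),
                       rep(as.integer(k) - 1L, length(idx)))
  avg <- if (rectify) apply(abs(g), c(1, 2), mean)
         else abs(apply(g, c(1, 2), mean))
  rng <- range(avg)
  if (rng[2] - rng[1] < .Machine$double.eps * max(1, abs(rng[2])))
    stop("degenerate saliency map: averaged gradients are constant")
  m <- (avg - rng[1]) / (rng[2] - rng[1])
  rownames(m) <- model@channels
  new("SaliencyMap", classLabel = as.character(classLabel), map = m,
      nTrials = length(idx), timeMs = epochTimes(epochs))
}

#' Rank contiguous high-saliency regions
#'
#' Thresholds the map at the `1 - topFraction` quantile and groups the
#' surviving cells into 4-connected clusters on the channel-by-time grid
#' (channel adjacency follows the montage's channel order), ranked by their
#' summed saliency.
#'
#' @param salMap a [SaliencyMap-class] (or a plain matrix).
#' @param topFraction fraction of cells to keep, in (0, 1].
#' @return data.frame, one row per cluster: `rank`, `n_cells`, `mass`,
#'   `channels`, `time_from_ms`, `time_to_ms`.
#' @export
featureRanking <- function(salMap, topFraction = 0.05) {
  if (is(salMap, "SaliencyMap")) {
    m <- salMap@map; timeMs <- salMap@timeMs
  } else {
    m <- salMap
    timeMs <- if (!is.null(colnames(m))) as.numeric(colnames(m))
              else seq_len(ncol(m))
  }
  if (!length(m)) stop("empty saliency map")
  if (topFraction <= 0 || topFraction > 1)
    stop("topFraction must be in (0, 1]")
  thr <- quantile(m, 1 - topFraction, type = 7)
  mask <- if (topFraction == 1) m >= -Inf else m > thr
  if (!any(mask)) mask <- m >= thr  # ties at the quantile
  lab <- matrix(0L, nrow(m), ncol(m))
  nextLab <- 0L
  cl <- list()
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nextLab <- nextLab + 1L
    queue <- start
    cells <- integer()
    lab[start] <- nextLab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      cells <- c(cells, cur)
      r <- (cur - 1) %% nrow(m) + 1
      cc <- (cur - 1) %/% nrow(m) + 1
      for (nb in c(if (r > 1) cur - 1, if (r < nrow(m)) cur + 1,
                   if (cc > 1) cur - nrow(m), if (cc < ncol(m)) cur + nrow(m))) {
        if (mask[nb] && lab[nb] == 0L) { lab[nb] <- nextLab; queue <- c(queue, nb) }
      }
    }
    cl[[nextLab]] <- cells
  }
  rows <- lapply(cl, function(cells) {
    r <- (cells - 1) %% nrow(m) + 1
    cc <- (cells - 1) %/% nrow(m) + 1
    data.frame(n_cells = length(cells), mass = sum(m[cells]),
               channels = paste(unique(rownames(m)[sort(unique(r))]),
                                collapse = ","),
               time_from_ms = min(timeMs[cc]), time_to_ms = max(timeMs[cc]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mass), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Score saliency localization against planted components
#'
#' For generator cohorts the planted (channel, time-window) cells are known;
#' this reports which share of the top-`topFraction` saliency mass falls
#' inside their union, and whether the map's global maximum does.
#'
#' @param salMap a [SaliencyMap-class].
#' @param planted list of components, each `list(channels=, windowMs=)`
#'   (e.g. the simulation's `metadata$groundTruth`).
#' @param topFraction top-mass fraction (default 0.05).
#' @return List with `share` (of top-cell mass inside the planted union),
#'   `argmaxInside`, `plantedFraction` (planted cells / all cells).
#' @export
saliencyLocalization <- function(salMap, planted, topFraction = 0.05) {
  stopifnot(is(salMap, "SaliencyMap"))
  m <- salMap@map
  inside <- matrix(FALSE, nrow(m), ncol(m))
  for (comp in planted) {
    chs <- intersect(comp$channels, rownames(m))
    tsel <- salMap@timeMs >= comp$windowMs[1] & salMap@timeMs <= comp$windowMs[2]
    inside[match(chs, rownames(m)), tsel] <- TRUE
  }
  thr <- quantile(m, 1 - topFraction, type = 7)
  top <- m > thr
  if (!any(top)) top <- m >= thr
  amax <- which.max(m)
  list(share = sum(m[top & inside]) / sum(m[top]),
       argmaxInside = inside[amax],
       plantedFraction = mean(inside))
}
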