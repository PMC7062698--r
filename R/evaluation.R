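# Leave-one-subject-out (LOOS) evaluation: splits, the binomial chance-level
# threshold, per-subject results and cohort summaries.

#' Leave-one-subject-out splits
#'
#' One split per subject as the test set; validation subjects are drawn
#' uniformly without replacement from the remainder with a per-split seed
#' derived from `seed`, and the rest train. The three sets are pairwise
#' disjoint and cover the cohort.
#'
#' @param subjectIds character vector of subject identifiers.
#' @param nVal validation subjects per split (4 by default).
#' @param seed integer seed.
#' @return List of splits, each with `test`, `val`, `train`.
#' @export
#' @examples
#' loosSplits(sprintf("S%02d", 1:6), nVal = 2, seed = 1)[[1]]
loosSplits <- function(subjectIds, nVal = 4, seed = 1L) {
  n <- length(subjectIds)
  if (n < nVal + 2)
    stop("cohort too small: need at least nVal + 2 = ", nVal + 2, " subjects")
  lapply(seq_len(n), function(i) {
    rest <- subjectIds[-i]
    set.seed(deriveSeed(seed, paste0("split", i)))
    val <- sample(rest, nVal)
    list(test = subjectIds[i], val = val, train = setdiff(rest, val))
  })
}

#' Binomial chance-level threshold
#'
#' The smallest accuracy (in percent) significantly above guessing for a
#' test set of `n` predictions over `c` classes: `100/n` times the smallest
#' `k` whose Binomial(n, 1/c) CDF reaches `1 - alpha` (the binomial inverse
#' CDF). An observed accuracy strictly above this threshold is significant at
#' level `alpha`.
#'
#' @param n test-set size (vectorised).
#' @param c number of classes (4 by default; `c = 1` degenerates to 100).
#' @param alpha significance level in (0, 1).
#' @return Threshold(s) in percent.
#' @export
#' @examples
#' chanceThreshold(346)         # about 28.9 for the 4-class problem
#' chanceThreshold(1e6)         # approaches 25
chanceThreshold <- function(n, c = 4, alpha = 0.05) {
  if (any(n < 1)) stop("n must be at least 1")
  if (c < 1) stop("c must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  100 * qbinom(1 - alpha, n, 1 / c) / n
}

#' Confusion matrix for the four-class problem
#'
#' Rows are the true labels, columns the predicted labels, in the fixed
#' class order of the label levels.
#'
#' @param trueLabels,predLabels equal-length factors (or vectors coercible to
#'   the trial-class levels).
#' @param normalize "none" for counts or "true" for row-normalized
#'   frequencies.
#' @return A square matrix.
#' @export
confusionMatrix <- function(trueLabels, predLabels,
                            normalize = c("none", "true")) {
  normalize <- match.arg(normalize)
  if (length(trueLabels) != length(predLabels))
    stop("label vectors must have equal length")
  lv <- if (is.factor(trueLabels)) levels(trueLabels) else trialClasses()
  bad <- setdiff(unique(c(as.character(trueLabels),
                          as.character(predLabels))), lv)
  if (length(bad))
    stop("labels outside the class enumeration: ", paste(bad, collapse = ", "))
  tt <- table(factor(trueLabels, levels = lv), factor(predLabels, levels = lv))
  m <- matrix(as.numeric(tt), nrow = length(lv),
              dimnames = list(true = lv, predicted = lv))
  if (normalize == "true") {
    rs <- rowSums(m)
    m <- m / ifelse(rs == 0, 1, rs)
  }
  m
}

#' Run the leave-one-subject-out evaluation of the network
#'
#' For every split, the classifier is trained on the training subjects'
#' trials, checkpointed against the validation subjects' trials, and
#' evaluated on the held-out subject. Each subject's accuracy is compared to
#' its own binomial chance threshold (the test-set size equals the number of
#' trials that subject contributes); the cohort summary reports the mean
#' accuracy, how many subjects exceed their threshold, the mean
#' above-threshold margin and a two-sided one-sample t statistic of
#' (accuracy - threshold) over the above-chance subjects, plus the pooled
#' (trial-weighted) row-normalized confusion matrix.
#'
#' @param epochsList named list of per-subject, model-ready
#'   [EpochSet-class] objects (same geometry).
#' @param config a [NetConfig-class].
#' @param nVal validation subjects per split.
#' @param maxEpochs,batchSize,lr training parameters (see [trainModel()]).
#' @param alpha significance level of the chance threshold.
#' @param seed seed controlling splits, initialization and training.
#' @param returnModels keep each split's trained model (for saliency).
#' @param verbose print one line per split.
#' @return List with `subjects` (one row per subject: `subject`, `n_test`,
#'   `accuracy`, `chance_threshold`, `above_chance`), `summary`,
#'   `confusions` (per-subject count matrices) and optionally `models`.
#' @export
runLoos <- function(epochsList, config = netConfig(), nVal = 4,
                    maxEpochs = 500, batchSize = 32, lr = 1e-3, alpha = 0.05,
                    seed = 1L, returnModels = FALSE, verbose = FALSE) {
  stopifnot(length(names(epochsList)) == length(epochsList))
  nEp <- vapply(epochsList, nTrials, 0L)
  if (any(nEp == 0)) {
    warning("excluding subject(s) with no surviving epochs: ",
            paste(names(epochsList)[nEp == 0], collapse = ", "))
    epochsList <- epochsList[nEp > 0]
  }
  ids <- names(epochsList)
  splits <- loosSplits(ids, nVal = nVal, seed = seed)
  ref <- epochsList[[1]]
  rows <- vector("list", length(splits))
  confusions <- vector("list", length(splits)); names(confusions) <- ids
  models <- if (returnModels) vector("list", length(splits)) else NULL
  if (returnModels) names(models) <- ids

  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    train <- bindEpochSets(epochsList[sp$train])
    val <- bindEpochSets(epochsList[sp$val])
    test <- epochsList[[sp$test]]
    model <- buildModel(config, channelNames(ref), nTimepoints(ref),
                        seed = deriveSeed(seed, paste0("init", i)))
    model <- trainModel(model, train, val, maxEpochs = maxEpochs,
                        batchSize = batchSize, lr = lr,
                        seed = deriveSeed(seed, paste0("train", i)))
    pred <- predictModel(model, test)
    acc <- 100 * mean(pred$predicted == epochLabels(test))
    thr <- chanceThreshold(nTrials(test), config@nClasses, alpha)
    rows[[i]] <- data.frame(subject = sp$test, n_test = nTrials(test),
                            accuracy = acc, chance_threshold = thr,
                            above_chance = acc > thr,
                            stringsAsFactors = FALSE)
    confusions[[sp$test]] <- confusionMatrix(epochLabels(test),
                                             pred$predicted)
    if (returnModels) models[[sp$test]] <- model
    if (verbose)
      message(sprintf("split %d/%d [%s]: accuracy %.1f%% (threshold %.1f%%)",
                      i, length(splits), sp$test, acc, thr))
  }
  subjects <- do.call(rbind, rows)
  out <- list(subjects = subjects,
              summary = cohortSummary(subjects, confusions),
              confusions = confusions)
  if (returnModels) out$models <- models
  out
}

#' Cohort roll-up of per-subject results
#'
#' @param subjects data.frame as returned in `runLoos()$subjects`.
#' @param confusions list of per-subject confusion count matrices.
#' @return List with `meanAccuracy`, `nAbove`, `fracAbove` (percent),
#'   `meanMargin` and `marginT` (over above-chance subjects), and
#'   `pooledConfusion` (trial-weighted, row-normalized).
#' @export
cohortSummary <- function(subjects, confusions = NULL) {
  above <- subjects$above_chance
  margin <- subjects$accuracy - subjects$chance_threshold
  marginT <- if (sum(above) >= 2 && sd(margin[above]) > 0)
    unname(t.test(margin[above])$statistic) else NA_real_
  pooled <- NULL
  if (!is.null(confusions) && length(confusions)) {
    tot <- Reduce(`+`, confusions)
    rs <- rowSums(tot)
    pooled <- tot / ifelse(rs == 0, 1, rs)
  }
  list(meanAccuracy = mean(subjects$accuracy),
       nAbove = sum(above),
       fracAbove = 100 * mean(above),
       meanMargin = if (any(above)) mean(margin[above]) else NA_real_,
       marginT = marginT,
       pooledConfusion = pooled)
}

#' Concatenate epoch sets along the trial dimension
#'
#' All sets must share montage, sampling rate, time axis and label levels.
#'
#' @param epochsList list of [EpochSet-class] objects.
#' @return A single [EpochSet-class] (subject id joins the parts).
#' @export
bindEpochSets <- function(epochsList) {
  if (length(epochsList) == 1) return(epochsList[[1]])
  ref <- epochsList[[1]]
  for (e in epochsList[-1]) {
    if (!identical(channelNames(e), channelNames(ref)) ||
        !isTRUE(all.equal(epochTimes(e), epochTimes(ref))))
      stop("epoch sets are not geometry-compatible")
  }
  data <- do.call(abind1, lapply(epochsList, epochData))
  labels <- factor(unlist(lapply(epochsList, function(e)
    as.character(epochLabels(e)))), levels = levels(ref@labels))
  new("EpochSet",
      subjectId = paste(vapply(epochsList, subjectId, ""), collapse = "+"),
      sfreq = ref@sfreq, data = data, timeMs = ref@timeMs, labels = labels,
      montage = ref@montage, csdApplied = ref@csdApplied, metadata = list())
}

# bind 3-d arrays along the first dimension
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(0, dim = c(n, d[2], d[3]))
  at <- 1
  for (p in parts) {
    k <- dim(p)[1]
    out[at:(at + k - 1), , ] <- p
    at <- at + k
  }
  out
}

#' Correlation between test-set size and accuracy
#'
#' Pearson correlation between the number of evaluated trials and the
#' per-subject accuracy, with `r_squared = r^2` as the share of explained
#' variance.
#'
#' @param subjects data.frame as returned in `runLoos()$subjects`
#'   (needs `n_test` and `accuracy`; at least 3 subjects).
#' @return List with `r`, `p`, `r_squared`, `n`.
#' @export
accuracyTrialCorrelation <- function(subjects) {
  if (nrow(subjects) < 3) stop("need at least 3 subjects")
  if (sd(subjects$accuracy) == 0 || sd(subjects$n_test) == 0)
    stop("correlation undefined: constant accuracy or test-set size")
  ct <- cor.test(subjects$n_test, subjects$accuracy)
  list(r = unname(ct$estimate), p = ct$p.value,
       r_squared = unname(ct$estimate)^2, n = nrow(subjects))
}

#' Dataset size bookkeeping
#'
#' Number of data points entering the decoding step: subjects x channels x
#' (sampling rate x analysed interval length) x trials.
#'
#' @param nSubjects,nChannels,sfreq,epochLengthS,nTrials study dimensions.
#' @return Total data-point count.
#' @export
#' @examples
#' dataPointCount(186, 60, 500, 1.5, 400)  # ~3.35e9
dataPointCount <- function(nSubjects, nChannels, sfreq, epochLengthS,
                           nTrials) {
  nSubjects * nChannels * (sfreq * epochLengthS) * nTrials
}
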