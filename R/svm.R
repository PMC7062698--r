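# Comparison classifier: radial-kernel support vector machine under the
# identical leave-one-subject-out protocol, with hyper-parameters selected on
# the validation subjects by grid search. The feature representation
# (flattened, standardized, time-decimated epochs) is a repository decision;
# standardization statistics are fitted on the training split only.

#' Hyper-parameter grid for the SVM baseline
#'
#' @param cost cost values C.
#' @param gamma RBF kernel widths (0.1..0.9 then 1..10 by default).
#' @return List with `cost` and `gamma`.
#' @export
svmGrid <- function(cost = c(0.01, 0.1, 1, 10, 100),
                    gamma = c(seq(0.1, 0.9, by = 0.1), 1:10)) {
  if (!length(cost) || !length(gamma) || any(cost <= 0) || any(gamma <= 0))
    stop("grids must be non-empty and positive")
  list(cost = cost, gamma = gamma)
}

#' Flatten epochs into an SVM feature matrix
#'
#' Takes every `decimation`-th timepoint of every channel and flattens each
#' trial to a vector; columns are standardized with statistics from `stats`
#' if given (test data), otherwise fitted from the data itself (training
#' data) and returned for reuse.
#'
#' @param epochs an [EpochSet-class].
#' @param decimation keep every decimation-th sample (>= 1).
#' @param stats optional list(center, scale) from a training call.
#' @return List with `x` (trials x features), `y` (labels) and `stats`.
#' @export
svmFeaturize <- function(epochs, decimation = 5, stats = NULL) {
  stopifnot(is(epochs, "EpochSet"), decimation >= 1)
  keep <- seq(1, nTimepoints(epochs), by = decimation)
  d <- epochData(epochs)[, , keep, drop = FALSE]
  x <- matrix(d, nrow = dim(d)[1])  # trials x (channels*timepoints)
  if (is.null(stats)) {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    scale[scale == 0] <- 1
    stats <- list(center = center, scale = scale)
  }
  x <- sweep(sweep(x, 2, stats$center), 2, stats$scale, "/")
  list(x = x, y = epochLabels(epochs), stats = stats)
}

#' Leave-one-subject-out evaluation of the SVM baseline
#'
#' Consumes the identical splits as [runLoos()] for the same seed. Per split,
#' every (cost, gamma) pair is fitted on the training subjects and scored on
#' the validation subjects; the best pair (ties resolved to the smallest
#' cost, then the smallest gamma) is refitted on the training data and
#' applied to the held-out subject. Multi-class classification is one-vs-one
#' with majority voting (the libsvm default). Summaries have the same shape
#' as the network's.
#'
#' @param epochsList named list of per-subject [EpochSet-class] objects.
#' @param grid an [svmGrid()].
#' @param decimation temporal decimation factor of the features.
#' @param nVal validation subjects per split.
#' @param alpha significance level of the chance threshold.
#' @param seed seed shared with the network evaluation.
#' @param verbose print one line per split.
#' @return List with `subjects`, `summary`, `confusions` and `chosen`
#'   (per-subject selected cost/gamma).
#' @export
runSvmLoos <- function(epochsList, grid = svmGrid(), decimation = 5,
                       nVal = 4, alpha = 0.05, seed = 1L, verbose = FALSE) {
  stopifnot(length(names(epochsList)) == length(epochsList))
  ids <- names(epochsList)
  splits <- loosSplits(ids, nVal = nVal, seed = seed)
  nClasses <- length(levels(epochLabels(epochsList[[1]])))
  rows <- vector("list", length(splits))
  confusions <- vector("list", length(splits)); names(confusions) <- ids
  chosen <- vector("list", length(splits)); names(chosen) <- ids

  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    tr <- svmFeaturize(bindEpochSets(epochsList[sp$train]), decimation)
    if (length(unique(tr$y)) < 2)
      stop("degenerate training set: a single class only")
    va <- svmFeaturize(bindEpochSets(epochsList[sp$val]), decimation,
                       stats = tr$stats)
    te <- svmFeaturize(epochsList[[sp$test]], decimation, stats = tr$stats)
    best <- NULL
    for (cost in sort(grid$cost)) {
      for (gamma in sort(grid$gamma)) {
        fit <- e1071::svm(tr$x, tr$y, kernel = "radial", cost = cost,
                          gamma = gamma, scale = FALSE)
        acc <- mean(predict(fit, va$x) == va$y)
        if (is.null(best) || acc > best$acc)
          best <- list(cost = cost, gamma = gamma, acc = acc)
      }
    }
    fit <- e1071::svm(tr$x, tr$y, kernel = "radial", cost = best$cost,
                      gamma = best$gamma, scale = FALSE)
    pred <- predict(fit, te$x)
    acc <- 100 * mean(pred == te$y)
    thr <- chanceThreshold(length(te$y), nClasses, alpha)
    rows[[i]] <- data.frame(subject = sp$test, n_test = length(te$y),
                            accuracy = acc, chance_threshold = thr,
                            above_chance = acc > thr,
                            stringsAsFactors = FALSE)
    confusions[[sp$test]] <- confusionMatrix(te$y, pred)
    chosen[[sp$test]] <- c(cost = best$cost, gamma = best$gamma)
    if (verbose)
      message(sprintf(
        "split %d/%d [%s]: SVM accuracy %.1f%% (C=%g, gamma=%g)",
        i, length(splits), sp$test, acc, best$cost, best$gamma))
  }
  subjects <- do.call(rbind, rows)
  list(subjects = subjects,
       summary = cohortSummary(subjects, confusions),
       confusions = confusions, chosen = chosen)
}
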