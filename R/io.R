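# Plain-text persistence: TSV matrices plus a JSON attribute sidecar. The
# epoch container stores the data (one row per trial x channel), the labels,
# the time axis and the acquisition attributes; montages and behavior tables
# are single TSV files.

#' Write / read a montage as TSV (name, x, y, z)
#' @param montage a [Montage-class].
#' @param path file path.
#' @export
writeMontage <- function(montage, path) {
  p <- channelPositions(montage)
  df <- data.frame(name = channelNames(montage),
                   x = format(p[, 1], digits = 17),
                   y = format(p[, 2], digits = 17),
                   z = format(p[, 3], digits = 17))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMontage
#' @export
readMontage <- function(path) {
  df <- read.delim(path)
  p <- as.matrix(df[, c("x", "y", "z")])
  p <- p / sqrt(rowSums(p^2))  # re-project onto the unit sphere
  rownames(p) <- df$name
  new("Montage", channels = df$name, positions = p)
}

#' Write / read an epoch set as TSV + JSON sidecar
#'
#' `prefix.data.tsv` holds the flattened data (trials*channels rows, one
#' column per timepoint, trial-major), `prefix.meta.json` the subject id,
#' sampling rate, labels, time axis, CSD flag and montage.
#'
#' @param epochs an [EpochSet-class].
#' @param prefix output path prefix.
#' @export
writeEpochSet <- function(epochs, prefix) {
  d <- epochData(epochs)
  flat <- matrix(aperm(d, c(2, 1, 3)), nrow = dim(d)[1] * dim(d)[2])
  write.table(format(flat, digits = 8, trim = TRUE),
              paste0(prefix, ".data.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  p <- channelPositions(getMontage(epochs))
  meta <- list(subject_id = subjectId(epochs), sfreq = samplingRate(epochs),
               n_trials = nTrials(epochs), csd_applied = epochs@csdApplied,
               labels = as.character(epochLabels(epochs)),
               label_levels = levels(epochLabels(epochs)),
               time_ms = epochTimes(epochs),
               channels = channelNames(epochs),
               positions = unname(apply(p, 1, c, simplify = FALSE)))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(prefix, ".meta.json"))
  invisible(prefix)
}

#' @rdname writeEpochSet
#' @export
readEpochSet <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, ".meta.json"),
                             simplifyVector = TRUE)
  flat <- as.matrix(read.delim(paste0(prefix, ".data.tsv"), header = FALSE))
  C <- length(meta$channels)
  nTr <- meta$n_trials
  data <- aperm(array(flat, dim = c(C, nTr, ncol(flat))), c(2, 1, 3))
  pos <- matrix(unlist(meta$positions), ncol = 3, byrow = TRUE)
  pos <- pos / sqrt(rowSums(pos^2))
  rownames(pos) <- meta$channels
  montage <- new("Montage", channels = meta$channels, positions = pos)
  new("EpochSet", subjectId = meta$subject_id, sfreq = meta$sfreq,
      data = data, timeMs = meta$time_ms,
      labels = factor(meta$labels, levels = meta$label_levels),
      montage = montage, csdApplied = meta$csd_applied, metadata = list())
}

#' Write / read a behavior table as TSV
#' @param behavior data.frame (subject, hand, conflict, rt_ms, correct).
#' @param path file path.
#' @export
writeBehaviorTable <- function(behavior, path) {
  write.table(behavior, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBehaviorTable
#' @export
readBehaviorTable <- function(path) {
  df <- read.delim(path)
  df$correct <- as.logical(df$correct)
  df
}

#' Write per-subject results and the cohort summary
#'
#' @param results output of [runLoos()] or [runSvmLoos()].
#' @param dir output directory (created if needed).
#' @export
writeLoosResults <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(results$subjects, file.path(dir, "subjects.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  s <- results$summary
  s$pooledConfusion <- NULL
  writeLines(jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA),
             file.path(dir, "summary.json"))
  if (!is.null(results$summary$pooledConfusion))
    write.table(results$summary$pooledConfusion,
                file.path(dir, "pooled_confusion.csv"), sep = ",",
                col.names = NA, quote = FALSE)
  invisible(dir)
}
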