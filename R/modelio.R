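# Model persistence (all plain text): layer weights and configuration as a
# JSON pair, training history as TSV.

#' Write / read a trained model
#'
#' Writes `<prefix>.weights.json` (all layer parameters, full precision),
#' `<prefix>.config.json` (architecture, geometry, class levels, checkpoint
#' index) and `<prefix>.history.tsv` (epoch, train_loss, val_loss).
#'
#' @param model a [TrainedModel-class].
#' @param prefix output path prefix.
#' @export
writeModel <- function(model, prefix) {
  stopifnot(is(model, "TrainedModel"))
  cfg <- model@config
  meta <- list(F1 = cfg@F1, D = cfg@D, F2 = cfg@F2,
               temporalKernel = cfg@temporalKernel,
               separableKernel = cfg@separableKernel,
               pool1 = cfg@pool1, pool2 = cfg@pool2, dropout = cfg@dropout,
               nClasses = cfg@nClasses, channels = model@channels,
               nTimepoints = model@nTimepoints,
               classLevels = model@classLevels, bestEpoch = model@bestEpoch)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(prefix, ".config.json"))
  writeLines(jsonlite::toJSON(model@weights, digits = NA, auto_unbox = FALSE,
                              matrix = "rowmajor"),
             paste0(prefix, ".weights.json"))
  write.table(model@history, paste0(prefix, ".history.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname writeModel
#' @export
readModel <- function(prefix) {
  meta <- jsonlite::fromJSON(paste0(prefix, ".config.json"))
  w <- jsonlite::fromJSON(paste0(prefix, ".weights.json"),
                          simplifyMatrix = TRUE)
  vecs <- c("bf", "g1", "b1", "g2", "b2", "g3", "b3",
            "rm1", "rv1", "rm2", "rv2", "rm3", "rv3")
  for (nm in vecs) w[[nm]] <- as.numeric(w[[nm]])
  for (nm in setdiff(names(w), vecs)) w[[nm]] <- as.matrix(w[[nm]])
  hist <- read.delim(paste0(prefix, ".history.tsv"))
  cfg <- netConfig(F1 = meta$F1, D = meta$D,
                   temporalKernel = meta$temporalKernel,
                   separableKernel = meta$separableKernel,
                   pool1 = meta$pool1, pool2 = meta$pool2,
                   dropout = meta$dropout, nClasses = meta$nClasses)
  new("TrainedModel", config = cfg, channels = meta$channels,
      nTimepoints = as.integer(meta$nTimepoints), weights = w,
      finalWeights = w, history = hist,
      bestEpoch = as.integer(meta$bestEpoch),
      classLevels = as.character(meta$classLevels))
}

#' Render a saliency map as a channel-by-time heatmap
#'
#' @param x a [SaliencyMap-class].
#' @param y ignored.
#' @param ... passed to [graphics::image()].
#' @export
setMethod("plot", signature(x = "SaliencyMap", y = "missing"),
          function(x, y, ...) {
  m <- x@map
  graphics::image(x = x@timeMs, y = seq_len(nrow(m)), z = t(m),
                  xlab = "time (ms)", ylab = "", yaxt = "n",
                  main = sprintf("saliency: %s (n=%d)", x@classLabel,
                                 x@nTrials), ...)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                 cex.axis = 0.5)
  invisible(x)
})
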