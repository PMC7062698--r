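# Behavioral statistics: closed-form 2x2 within-subject (repeated measures)
# ANOVA on the hand-by-conflict cell means, with partial eta squared, plus
# post-hoc paired t-tests. Each 1-df within effect is computed from
# per-subject contrast scores, where F equals the squared paired t of the
# contrast; with single-df effects in a 2x2 design a sphericity correction
# is vacuous and none is applied.

#' Per-subject cell means of the behavior table
#'
#' Aggregates the trial-level table to one row per subject x hand x conflict
#' cell: mean correct-trial RT and the error rate.
#'
#' @param behavior data.frame with columns subject, hand, conflict, rt_ms,
#'   correct (as produced by [simulateSubject()]/[simulateCohort()]).
#' @return data.frame with columns subject, hand, conflict, mean_rt_ms,
#'   error_rate.
#' @export
behaviorCellMeans <- function(behavior) {
  need <- c("subject", "hand", "conflict", "rt_ms", "correct")
  if (!all(need %in% names(behavior)))
    stop("behavior table must have columns: ", paste(need, collapse = ", "))
  err <- aggregate(list(error_rate = !behavior$correct),
                   behavior[c("subject", "hand", "conflict")], mean)
  ok <- behavior[behavior$correct, , drop = FALSE]
  rt <- aggregate(list(mean_rt_ms = ok$rt_ms),
                  ok[c("subject", "hand", "conflict")], mean)
  out <- merge(err, rt, all.x = TRUE)
  out[order(out$subject, out$hand, out$conflict), ]
}

.cellWide <- function(cells, outcome) {
  col <- switch(outcome, rt = "mean_rt_ms", error = "error_rate",
                stop("outcome must be 'rt' or 'error'"))
  subjects <- unique(cells$subject)
  wide <- matrix(NA_real_, length(subjects), 4,
                 dimnames = list(subjects,
                                 c("left_nonconflict", "left_conflict",
                                   "right_nonconflict", "right_conflict")))
  for (i in seq_len(nrow(cells))) {
    key <- paste0(cells$hand[i], "_", cells$conflict[i])
    wide[as.character(cells$subject[i]), key] <- cells[[col]][i]
  }
  bad <- rownames(wide)[apply(wide, 1, anyNA)]
  if (length(bad))
    stop("incomplete 2x2 design for subject(s): ", paste(bad, collapse = ", "))
  wide
}

#' 2x2 repeated-measures ANOVA (hand x conflict)
#'
#' Main effects and interaction from per-subject contrast scores; for each
#' 1-df effect, F is the squared paired t of the contrast, with df (1, n-1)
#' and partial eta squared = SS_effect / (SS_effect + SS_error) =
#' F / (F + n - 1).
#'
#' @param cells output of [behaviorCellMeans()] (complete 2x2 design per
#'   subject, at least 3 subjects).
#' @param outcome "rt" (mean correct RT) or "error" (error rate).
#' @return data.frame with one row per effect (`hand`, `conflict`,
#'   `interaction`): `F`, `df1`, `df2`, `p`, `partial_eta_sq`, `mean_effect`.
#' @export
#' @examples
#' coh <- simulateCohort(3, simulationConfig(nTrials = 48, nChannels = 8))
#' rmAnova2x2(behaviorCellMeans(coh$behavior), "rt")
rmAnova2x2 <- function(cells, outcome = c("rt", "error")) {
  outcome <- match.arg(outcome)
  wide <- .cellWide(cells, outcome)
  n <- nrow(wide)
  if (n < 3) stop("need at least 3 subjects")
  ln <- wide[, "left_nonconflict"]; lc <- wide[, "left_conflict"]
  rn <- wide[, "right_nonconflict"]; rc <- wide[, "right_conflict"]
  contrasts <- list(
    hand = (ln + lc) / 2 - (rn + rc) / 2,
    conflict = (lc + rc) / 2 - (ln + rn) / 2,
    interaction = (lc - ln) - (rc - rn))
  rows <- lapply(names(contrasts), function(eff) {
    x <- contrasts[[eff]]
    s <- sd(x)
    t <- if (s == 0) { if (mean(x) == 0) 0 else Inf }
         else mean(x) / (s / sqrt(n))
    F <- t^2
    p <- if (is.infinite(F)) 0 else pf(F, 1, n - 1, lower.tail = FALSE)
    data.frame(effect = eff, F = F, df1 = 1, df2 = n - 1, p = p,
               partial_eta_sq = if (is.infinite(F)) 1 else F / (F + n - 1),
               mean_effect = mean(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired t-test
#'
#' Classical paired t statistic with df = n - 1 and a two-sided p value.
#' Zero variance of the differences with a nonzero mean yields an infinite t
#' (signalled with a warning); identical vectors give t = 0.
#'
#' @param a,b equal-length per-subject values, paired by position.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @export
#' @examples
#' pairedT(c(5, 7, 9), c(4, 6, 10))
pairedT <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- a - b
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1, p = 1, mean_diff = 0))
    warning("zero variance of differences with nonzero mean: infinite t")
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                mean_diff = mean(d)))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1), mean_diff = mean(d))
}
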