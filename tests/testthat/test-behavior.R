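# Behavioral statistics: contrast-based 2x2 repeated-measures ANOVA against
# an independent sums-of-squares decomposition (and aov with Error strata),
# paired t against the textbook formula, and invariances.

# hand-built 4-subject table with a clear conflict effect
.handTable <- function() {
  subj <- rep(sprintf("P%d", 1:4), each = 4)
  hand <- rep(c("left", "left", "right", "right"), 4)
  conflict <- rep(c("nonconflict", "conflict"), 8)
  rt <- c(400, 435, 395, 430,
          410, 450, 400, 445,
          390, 420, 385, 425,
          405, 445, 398, 440)
  data.frame(subject = subj, hand = hand, conflict = conflict,
             mean_rt_ms = rt, error_rate = rt / 5000)
}

test_that("ANOVA F values match a direct sums-of-squares decomposition", {
  tbl <- .handTable()
  res <- rmAnova2x2(tbl, "rt")

  # oracle: textbook two-way within-subject SS decomposition from cell means
  y <- tbl$mean_rt_ms
  subj <- factor(tbl$subject); hand <- factor(tbl$hand)
  conf <- factor(tbl$conflict)
  n <- nlevels(subj)
  gm <- mean(y)
  ys <- tapply(y, subj, mean)
  ya <- tapply(y, hand, mean); yb <- tapply(y, conf, mean)
  ysa <- tapply(y, list(subj, hand), mean)
  ysb <- tapply(y, list(subj, conf), mean)
  yab <- tapply(y, list(hand, conf), mean)
  ssA <- 2 * n * sum((ya - gm)^2)
  ssAS <- 2 * sum((ysa - outer(ys, ya, "+") + gm)^2)
  ssB <- 2 * n * sum((yb - gm)^2)
  ssBS <- 2 * sum((ysb - outer(ys, yb, "+") + gm)^2)
  ssAB <- n * sum((sweep(sweep(yab, 1, ya), 2, yb) + gm)^2)
  resid <- y - ysa[cbind(subj, hand)] - ysb[cbind(subj, conf)] -
    yab[cbind(hand, conf)] + ys[subj] + ya[hand] + yb[conf] - gm
  ssABS <- sum(resid^2)
  ss <- list(hand = c(ssA, ssAS), conflict = c(ssB, ssBS),
             interaction = c(ssAB, ssABS))
  for (eff in names(ss)) {
    Fo <- ss[[eff]][1] / (ss[[eff]][2] / (n - 1))
    expect_equal(res$F[res$effect == eff], Fo, tolerance = 1e-8)
    expect_equal(res$partial_eta_sq[res$effect == eff],
                 ss[[eff]][1] / sum(ss[[eff]]), tolerance = 1e-8)
  }

  # second independent route: aov with within-subject error strata
  fit <- summary(stats::aov(mean_rt_ms ~ hand * conflict +
                              Error(subject / (hand * conflict)),
                            data = tbl))
  aovF <- c(hand = fit[["Error: subject:hand"]][[1]]$`F value`[1],
            conflict = fit[["Error: subject:conflict"]][[1]]$`F value`[1],
            interaction = fit[["Error: subject:hand:conflict"]][[1]]$`F value`[1])
  expect_equal(res$F, unname(aovF[res$effect]), tolerance = 1e-8)
})

test_that("each 1-df F equals the squared paired t of its contrast", {
  tbl <- .handTable()
  res <- rmAnova2x2(tbl, "rt")
  wide <- matrix(tbl$mean_rt_ms, 4, 4, byrow = TRUE)  # LN LC RN RC per row
  tt <- pairedT((wide[, 2] + wide[, 4]) / 2, (wide[, 1] + wide[, 3]) / 2)
  expect_equal(res$F[res$effect == "conflict"], tt$t^2, tolerance = 1e-10)
  expect_equal(res$p[res$effect == "conflict"], tt$p, tolerance = 1e-10)
})

test_that("ANOVA nulls, errors and invariances", {
  tbl <- .handTable()
  flat <- tbl
  flat$mean_rt_ms <- rep(tapply(tbl$mean_rt_ms, tbl$subject, mean)[tbl$subject])
  res0 <- rmAnova2x2(flat, "rt")
  expect_equal(res0$F, rep(0, 3), tolerance = 1e-20)
  # permutation of subject rows changes nothing
  perm <- sample(nrow(tbl))
  expect_equal(rmAnova2x2(tbl[perm, ], "rt")$F, rmAnova2x2(tbl, "rt")$F)
  # adding a constant changes nothing (location invariance)
  shifted <- tbl; shifted$mean_rt_ms <- shifted$mean_rt_ms + 500
  expect_equal(rmAnova2x2(shifted, "rt")$F, rmAnova2x2(tbl, "rt")$F,
               tolerance = 1e-8)
  # incomplete designs name the offending subject
  expect_error(rmAnova2x2(tbl[-1, ], "rt"), "P1")
})

test_that("paired t matches the textbook computation on 5 hand-built pairs", {
  a <- c(12, 15, 11, 17, 14)
  b <- c(10, 14, 12, 13, 11)
  d <- a - b                       # 2, 1, -1, 4, 3
  tManual <- mean(d) / (sd(d) / sqrt(5))
  out <- pairedT(a, b)
  expect_equal(out$t, tManual, tolerance = 1e-12)
  expect_equal(out$df, 4)
  expect_equal(out$p, 2 * pt(-abs(tManual), 4), tolerance = 1e-12)
  expect_equal(out$mean_diff, 1.8)
  # degenerate cases
  same <- pairedT(a, a)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_warning(inf <- pairedT(a, a - 2), "infinite")
  expect_equal(inf$t, Inf)
})

test_that("a planted conflict effect is detected with the right direction", {
  coh <- simulateCohort(5, simulationConfig(nTrials = 160, nChannels = 8,
                                            sfreq = 100, seed = 31))
  cells <- behaviorCellMeans(coh$behavior)
  res <- rmAnova2x2(cells, "rt")
  conflictRow <- res[res$effect == "conflict", ]
  expect_lt(conflictRow$p, 0.05)
  expect_gt(conflictRow$mean_effect, 0)  # conflict slower than non-conflict
  resErr <- rmAnova2x2(cells, "error")
  expect_gt(resErr[resErr$effect == "conflict", "mean_effect"], 0)
})
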