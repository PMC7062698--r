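# Splits, the binomial chance threshold, confusion matrices and summaries.

test_that("LOOS splits are disjoint, exhaustive and seeded", {
  ids <- sprintf("S%02d", 1:6)
  sp <- loosSplits(ids, nVal = 2, seed = 7)
  expect_length(sp, 6)
  for (i in seq_along(sp)) {
    s <- sp[[i]]
    expect_equal(s$test, ids[i])
    expect_length(s$val, 2)
    expect_length(s$train, 3)
    expect_length(intersect(s$test, c(s$val, s$train)), 0)
    expect_length(intersect(s$val, s$train), 0)
    expect_setequal(c(s$test, s$val, s$train), ids)
  }
  expect_identical(sp, loosSplits(ids, nVal = 2, seed = 7))
  expect_false(identical(sp, loosSplits(ids, nVal = 2, seed = 8)))
  expect_error(loosSplits(ids[1:3], nVal = 2), "too small")
})

test_that("chanceThreshold equals the brute-force binomial quantile", {
  # oracle: accumulate the binomial pmf until 1 - alpha is reached
  bruteThreshold <- function(n, c, alpha) {
    pk <- dbinom(0:n, n, 1 / c)
    k <- which(cumsum(pk) >= 1 - alpha)[1] - 1
    100 * k / n
  }
  for (n in c(10, 37, 100, 346)) {
    expect_equal(chanceThreshold(n, 4, 0.05), bruteThreshold(n, 4, 0.05))
    expect_equal(chanceThreshold(n, 2, 0.01), bruteThreshold(n, 2, 0.01))
  }
  expect_equal(chanceThreshold(346, 4, 0.05), 100 * 100 / 346)
  # degenerate one-class problem: success probability 1
  expect_equal(chanceThreshold(50, 1, 0.05), 100)
  expect_error(chanceThreshold(100, 4, 1.5), "alpha")
})

test_that("the threshold stays above 100/c and falls toward it with n", {
  n <- c(50, 200, 1000, 10000)
  thr <- chanceThreshold(n, 4, 0.05)
  expect_true(all(thr >= 25))
  expect_true(all(diff(thr) < 0))
  expect_lt(chanceThreshold(1e6, 4, 0.05) - 25, 0.1)
})

test_that("confusion matrices count and normalize as declared", {
  truth <- factor(rep(trialClasses(), each = 2), levels = trialClasses())
  perfect <- confusionMatrix(truth, truth, normalize = "true")
  expect_equal(unname(perfect), diag(4))
  # hand-counted 8-trial example
  pred <- factor(c("left_nonconflict", "left_conflict",   # 1 hit, 1 miss
                   "left_conflict", "left_conflict",      # 2 hits
                   "right_nonconflict", "left_nonconflict",
                   "right_conflict", "right_conflict"),
                 levels = trialClasses())
  cm <- confusionMatrix(truth, pred)
  expect_equal(sum(cm), 8)
  expect_equal(unname(diag(cm)), c(1, 2, 1, 2))
  expect_equal(cm["left_nonconflict", "left_conflict"], 1)
  rn <- confusionMatrix(truth, pred, normalize = "true")
  expect_equal(unname(rowSums(rn)), rep(1, 4))
  expect_error(confusionMatrix(truth, rep("nope", 8)), "outside")
})

test_that("accuracy-by-trial-count correlation behaves at the edges", {
  subjects <- data.frame(n_test = c(100, 150, 200, 250),
                         accuracy = 10 + 0.1 * c(100, 150, 200, 250))
  out <- accuracyTrialCorrelation(subjects)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(out$r_squared, out$r^2)
  subjects$accuracy <- 40
  expect_error(accuracyTrialCorrelation(subjects), "constant")
})

test_that("runLoos assembles per-subject rows and a consistent summary", {
  eps <- lapply(1:4, function(i)
    makeTestEpochs(nTrials = 16, nChannels = 6, nTimepoints = 96, seed = i,
                   subject = sprintf("S%02d", i)))
  names(eps) <- sprintf("S%02d", 1:4)
  res <- runLoos(eps, netConfig(4, 2), nVal = 1, maxEpochs = 2, seed = 3)
  expect_equal(nrow(res$subjects), 4)
  expect_equal(res$subjects$n_test, rep(16L, 4))
  for (s in res$subjects$subject) {
    cm <- res$confusions[[s]]
    expect_equal(sum(cm), 16)
    row <- res$subjects[res$subjects$subject == s, ]
    expect_equal(row$accuracy, 100 * sum(diag(cm)) / sum(cm))
    expect_equal(row$above_chance, row$accuracy > row$chance_threshold)
  }
  expect_equal(unname(rowSums(res$summary$pooledConfusion)), rep(1, 4),
               tolerance = 1e-9)
  expect_lte(res$summary$nAbove, 4)
  # pooled confusion equals the sum of per-subject counts, row-normalized
  tot <- Reduce(`+`, res$confusions)
  expect_equal(unname(res$summary$pooledConfusion),
               unname(tot / rowSums(tot)), tolerance = 1e-12)
})

test_that("data-point bookkeeping multiplies the study dimensions", {
  expect_equal(dataPointCount(186, 60, 500, 1.5, 400), 3.348e9)
  expect_equal(dataPointCount(2, 8, 100, 1, 10), 2 * 8 * 100 * 10)
})
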