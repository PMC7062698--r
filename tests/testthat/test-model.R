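# Network construction, parameter bookkeeping, class weights, training and
# prediction behavior.

test_that("parameter count matches the per-layer formulas", {
  # per-layer parameter formulas: temporal conv F1*64, batch norms 2*F,
  # depthwise C*D*F1, separable 16*F2 + F2*F2, dense (F2*T/32)*N + N
  cfg <- netConfig(8, 2)
  model <- buildModel(cfg, channels = 60, nTimepoints = 750)
  expected <- 8 * 64 + 2 * 8 +      # temporal conv + BN
    60 * 2 * 8 + 2 * 16 +           # depthwise (960) + BN
    16 * 16 + 16 * 16 + 2 * 16 +    # separable depthwise + pointwise + BN
    (16 * 23) * 4 + 4               # dense over the 368-long flatten
  expect_equal(nParameters(model), expected)
  expect_equal(expected, 3540)
  # flatten length = F2 * floor(floor(T/4)/8) = 16 * 23 = 368
  expect_equal(length(model@weights$Wf) / 4, 368)
  # the count depends only on (C, T, F1, D, N), not on data volume
  expect_equal(nParameters(buildModel(cfg, 60, 750, seed = 99)), expected)
})

test_that("class weights are inverse proportions with majority = 1", {
  expect_equal(unname(classWeights(c(100, 100, 100, 50))), c(1, 1, 1, 2))
  expect_equal(unname(classWeights(c(80, 80, 80, 80))), rep(1, 4))
  expect_equal(unname(classWeights(c(200, 100, 100, 100))), c(1, 2, 2, 2))
  expect_error(classWeights(c(10, 0, 5, 5)), "positive")
})

test_that("prediction returns proper softmax probabilities", {
  ep <- makeTestEpochs(nTrials = 10, nChannels = 8, nTimepoints = 96)
  model <- buildModel(netConfig(4, 2), channelNames(ep), 96)
  model@classLevels <- trialClasses()
  pr <- predictModel(model, ep)
  expect_equal(rowSums(pr$probabilities), rep(1, 10), tolerance = 1e-6)
  # probabilities recompute from the exposed pre-softmax scores
  soft <- t(apply(pr$scores, 1, function(s) exp(s - max(s)) / sum(exp(s - max(s)))))
  expect_equal(unname(pr$probabilities), unname(soft), tolerance = 1e-5)
  # zeroed dense layer -> exactly uniform output
  model0 <- model
  model0@weights$Wf[] <- 0; model0@weights$bf[] <- 0
  expect_equal(unname(predictModel(model0, ep)$probabilities),
               matrix(0.25, 10, 4), tolerance = 1e-6)
})

test_that("the single-precision forward pass matches the double reference", {
  ep <- makeTestEpochs(nTrials = 4, nChannels = 8, nTimepoints = 96, seed = 5)
  model <- buildModel(netConfig(8, 2), channelNames(ep), 96, seed = 3)
  model@weights <- refNetWeights(model)
  model@classLevels <- trialClasses()
  sc <- predictModel(model, ep)$scores
  for (i in 1:4) {
    ref <- refNetForward(epochData(ep)[i, , ], model@weights, model@config)
    expect_equal(unname(sc[i, ]), ref, tolerance = 1e-4)
  }
})

test_that("a linearly separable toy is learned to 100% within 50 epochs", {
  set.seed(7)
  n <- 96; C <- 4; T <- 96
  lab <- factor(rep(c("left_nonconflict", "right_nonconflict"), each = n / 2),
                levels = trialClasses()[c(1, 3)])
  ep <- makeTestEpochs(nTrials = n, nChannels = C, nTimepoints = T, seed = 7,
                       labels = lab)
  ep@data <- ep@data * 0.3
  ep@data[, 2, ] <- ep@data[, 2, ] +
    ifelse(as.integer(lab) == 1, -1, 1)  # one channel carries the class sign
  model <- buildModel(netConfig(4, 2, nClasses = 2), channelNames(ep), T,
                      seed = 3)
  fit <- trainModel(model, ep, ep, maxEpochs = 50, batchSize = 32, seed = 11)
  acc <- mean(predictModel(fit, ep)$predicted == lab)
  expect_equal(acc, 1)
  expect_lte(fit@history$val_loss[bestEpoch(fit)], min(fit@history$val_loss))
})

test_that("training is reproducible for a fixed seed", {
  ep <- makeTestEpochs(nTrials = 24, nChannels = 6, nTimepoints = 96, seed = 2)
  model <- buildModel(netConfig(4, 2), channelNames(ep), 96, seed = 5)
  f1 <- trainModel(model, ep, ep, maxEpochs = 8, seed = 42)
  f2 <- trainModel(model, ep, ep, maxEpochs = 8, seed = 42)
  expect_identical(f1@history, f2@history)
  expect_identical(f1@weights, f2@weights)
  f3 <- trainModel(model, ep, ep, maxEpochs = 8, seed = 43)
  expect_false(identical(f3@history$val_loss, f1@history$val_loss))
})

test_that("prediction has no cross-trial leakage and no dropout variability", {
  ep <- makeTestEpochs(nTrials = 12, nChannels = 6, nTimepoints = 96, seed = 4)
  model <- buildModel(netConfig(4, 2), channelNames(ep), 96, seed = 8)
  model@classLevels <- trialClasses()
  p1 <- predictModel(model, ep)$probabilities
  p2 <- predictModel(model, ep)$probabilities
  expect_identical(p1, p2)  # dropout disabled at inference
  perm <- sample(12)
  epP <- ep
  epP@data <- ep@data[perm, , , drop = FALSE]
  epP@labels <- ep@labels[perm]
  expect_equal(predictModel(model, epP)$probabilities, p1[perm, ],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("geometry and label-set mismatches are rejected", {
  ep <- makeTestEpochs(nTrials = 8, nChannels = 6, nTimepoints = 96)
  model <- buildModel(netConfig(4, 2), channelNames(ep), 96)
  bad <- makeTestEpochs(nTrials = 8, nChannels = 6, nTimepoints = 128)
  expect_error(predictModel(model, bad), "does not match")
  expect_error(buildModel(netConfig(4, 2), 6, 32), "temporal kernel")
  onecls <- ep
  onecls@labels <- factor(rep("left_conflict", 8), levels = trialClasses())
  expect_error(trainModel(model, onecls, onecls), "missing")
})

test_that("selectFilterConfig returns a candidate and honors dominance", {
  # single candidate is returned unchanged
  ep <- makeTestEpochs(nTrials = 20, nChannels = 6, nTimepoints = 96)
  eps <- list(S1 = ep,
              S2 = makeTestEpochs(nTrials = 20, nChannels = 6,
                                  nTimepoints = 96, seed = 2, subject = "S2"),
              S3 = makeTestEpochs(nTrials = 20, nChannels = 6,
                                  nTimepoints = 96, seed = 3, subject = "S3"))
  out <- selectFilterConfig(eps, candidates = list(c(4, 2)), nVal = 1,
                            maxEpochs = 2, seed = 1)
  expect_equal(out$config@F1, 4L)
  expect_true(all(names(out$meanAccuracy) == "(4,2)"))
})
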