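# Input-gradient saliency: agreement with finite differences of the
# double-precision reference forward pass, structural zeros, normalization
# and feature ranking.

test_that("analytic gradients match central finite differences of the reference", {
  ep <- makeTestEpochs(nTrials = 1, nChannels = 8, nTimepoints = 96, seed = 5)
  model <- buildModel(netConfig(8, 2), channelNames(ep), 96, seed = 3)
  model@weights <- refNetWeights(model)
  model@classLevels <- trialClasses()
  x <- epochData(ep)[1, , ]
  cls <- 3L
  g <- cppNetInputGrad(array(x, dim = c(dim(x), 1)), model@weights,
                       eegconflict:::.cfgList(model@config), cls - 1L)[, , 1]
  gmax <- max(abs(g))
  eps <- 1e-4
  set.seed(11)
  for (i in 1:20) {
    ch <- sample(8, 1); tt <- sample(96, 1)
    xp <- x; xp[ch, tt] <- xp[ch, tt] + eps
    xm <- x; xm[ch, tt] <- xm[ch, tt] - eps
    fd <- (refNetForward(xp, model@weights, model@config)[cls] -
             refNetForward(xm, model@weights, model@config)[cls]) / (2 * eps)
    # relative to the larger of the two values, floored at 1% of the map
    # scale so near-zero cells compare at single precision sensibly
    denom <- max(abs(fd), abs(g[ch, tt]), 0.01 * gmax)
    expect_lt(abs(fd - g[ch, tt]) / denom, 1e-3)
  }
})

test_that("saliency vanishes on channels the first layer ignores", {
  ep <- makeTestEpochs(nTrials = 2, nChannels = 6, nTimepoints = 96, seed = 2)
  model <- buildModel(netConfig(4, 2), channelNames(ep), 96, seed = 4)
  model@classLevels <- trialClasses()
  # zero the depthwise spatial weights of channel 3: no gradient path
  model@weights$Wd[, 3] <- 0
  s <- trialSaliency(model, epochData(ep)[1, , ], 2)
  expect_equal(dim(s), c(6, 96))
  expect_true(all(s >= 0))
  expect_equal(max(s[3, ]), 0)
})

test_that("class-averaged maps are min-max normalized with scale-invariant argmax", {
  ep <- makeTestEpochs(nTrials = 12, nChannels = 6, nTimepoints = 96, seed = 6)
  model <- buildModel(netConfig(4, 2), channelNames(ep), 96, seed = 9)
  model@classLevels <- trialClasses()
  sal <- classAverageSaliency(model, ep, "left_conflict")
  expect_s4_class(sal, "SaliencyMap")
  expect_equal(min(sal@map), 0)
  expect_equal(max(sal@map), 1)
  expect_equal(sal@nTrials, sum(epochLabels(ep) == "left_conflict"))
  # positive input scaling rescales raw gradients but not the argmax
  ep2 <- ep
  ep2@data <- ep@data * 3
  sal2 <- classAverageSaliency(model, ep2, "left_conflict")
  expect_equal(which.max(sal2@map), which.max(sal@map))
  expect_error(classAverageSaliency(model, ep, "no_such_class"), "no trials")
  # constant raw map is flagged, not divided by zero
  degenerate <- model
  degenerate@weights$W1[] <- 0
  expect_error(classAverageSaliency(degenerate, ep, "left_conflict"),
               "degenerate")
})

test_that("feature ranking clusters and orders planted hotspots", {
  m <- matrix(0, 6, 40, dimnames = list(sprintf("ch%d", 1:6), NULL))
  sal <- new("SaliencyMap", classLabel = "left_conflict", map = m,
             nTrials = 1L, timeMs = seq(0, by = 10, length.out = 40))
  # a single nonzero cell forms exactly one single-cell cluster
  m1 <- m; m1[3, 10] <- 1
  sal@map <- m1
  fr <- featureRanking(sal, 0.05)
  expect_equal(nrow(fr), 1)
  expect_equal(fr$n_cells, 1)
  # two disjoint blocks with 2:1 amplitude rank in that order
  m2 <- m
  m2[2, 5:8] <- 1.0          # strong early cluster
  m2[5, 25:28] <- 0.5        # weaker late cluster
  sal@map <- m2
  fr2 <- featureRanking(sal, 8 / 240)
  expect_equal(nrow(fr2), 2)
  expect_gt(fr2$mass[1], fr2$mass[2])
  expect_equal(fr2$channels[1], "ch2")
  expect_lt(fr2$time_to_ms[1], fr2$time_from_ms[2])
  # topFraction = 1 covers every cell
  fr3 <- featureRanking(sal, 1)
  expect_equal(sum(fr3$n_cells), length(m2))
})
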