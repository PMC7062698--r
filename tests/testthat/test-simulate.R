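# Generator properties: class balance, determinism, behavioral effects,
# null construction, and the separability monotonicity of the planted N1.

test_that("stimulus side is a pure function of hand and conflict", {
  expect_equal(stimulusSide(c("left", "left", "right", "right"),
                            c("nonconflict", "conflict",
                              "nonconflict", "conflict")),
               c("left", "right", "right", "left"))
  expect_length(trialClasses(), 4)
  expect_false(anyDuplicated(trialClasses()) > 0)
  lab <- trialClassLabel("left", "conflict")
  expect_identical(levels(lab), trialClasses())
})

test_that("simulated subjects have balanced classes and valid events", {
  cfg <- simulationConfig(nTrials = 42, nChannels = 16, sfreq = 200, seed = 4)
  sub <- simulateSubject(cfg, "S01")
  rec <- sub$recording
  counts <- table(trialClassLabel(rec@events$hand, rec@events$conflict))
  expect_true(max(counts) - min(counts) <= 1)
  expect_true(all(diff(rec@events$onset_sample) > 0))
  expect_true(all(rec@events$rt_ms > 0))
  expect_equal(nrow(sub$behavior), 42)
})

test_that("the same seed reproduces a recording bit for bit; different subjects differ", {
  cfg <- simulationConfig(nTrials = 8, nChannels = 8, sfreq = 100, seed = 9)
  a <- simulateSubject(cfg, "S01")$recording
  b <- simulateSubject(cfg, "S01")$recording
  expect_identical(a@data, b@data)
  c <- simulateSubject(cfg, "S02")$recording
  expect_false(isTRUE(all.equal(a@data[, seq_len(min(ncol(a@data), ncol(c@data)))],
                                c@data[, seq_len(min(ncol(a@data), ncol(c@data)))])))
})

test_that("behavior reproduces the Simon effect at scale", {
  cfg <- simulationConfig(nTrials = 400, nChannels = 8, sfreq = 100, seed = 2,
                          noiseScaleUv = 0)
  beh <- do.call(rbind, lapply(1:4, function(i)
    simulateSubject(cfg, sprintf("S%02d", i))$behavior))
  ok <- beh[beh$correct, ]
  rtc <- mean(ok$rt_ms[ok$conflict == "conflict"])
  rtn <- mean(ok$rt_ms[ok$conflict == "nonconflict"])
  # planted 37 ms conflict cost, recovered within sampling error
  expect_gt(rtc - rtn, 20)
  expect_lt(rtc - rtn, 55)
  errc <- mean(!beh$correct[beh$conflict == "conflict"])
  errn <- mean(!beh$correct[beh$conflict == "nonconflict"])
  expect_gt(errc, errn)
})

test_that("zero-amplitude components give class-indistinguishable mean epochs", {
  cfg <- simulationConfig(nTrials = 80, nChannels = 8, sfreq = 100, seed = 6,
                          n1AmplitudeUv = 0, conflictAmplitudeUv = 0,
                          motorAmplitudeUv = 0)
  sub <- simulateSubject(cfg, "S01")
  ep <- segmentEpochs(sub$recording, correctOnly = FALSE)
  lab <- epochLabels(ep)
  conflict <- grepl("_conflict$", as.character(lab))
  # per-channel t-tests of conflict vs non-conflict mean amplitude in the
  # conflict window: at alpha = 0.05 expect no systematic rejections
  sel <- epochTimes(ep) >= 300 & epochTimes(ep) <= 400
  p <- vapply(seq_len(nChannels(ep)), function(ch) {
    a <- rowMeans(epochData(ep)[conflict, ch, sel])
    b <- rowMeans(epochData(ep)[!conflict, ch, sel])
    t.test(a, b)$p.value
  }, 0)
  expect_lt(sum(p < 0.05), 3)  # 8 tests at the nominal level
})

test_that("noise-free positive-amplitude epochs repeat exactly within class", {
  cfg <- simulationConfig(nTrials = 16, nChannels = 16, sfreq = 200, seed = 3,
                          noiseScaleUv = 0, motorAmplitudeUv = 0)
  sub <- simulateSubject(cfg, "S01")
  ep <- cropForModel(segmentEpochs(sub$recording, correctOnly = FALSE),
                     0, 280)
  lab <- as.character(epochLabels(ep))
  # motor component is off and RT jitter only affects t > RT; within the
  # stimulus-locked windows, trials of one class are identical
  for (cl in unique(lab)) {
    idx <- which(lab == cl)
    for (i in idx[-1])
      expect_equal(epochData(ep)[i, , ], epochData(ep)[idx[1], , ],
                   tolerance = 1e-12)
  }
})

test_that("increasing the N1 amplitude never hurts stimulus-side separability", {
  # linear-probe separability on the injected window, same noise seed
  sep <- vapply(c(0, 4, 10), function(a) {
    cfg <- simulationConfig(nTrials = 60, nChannels = 16, sfreq = 200,
                            seed = 12, n1AmplitudeUv = a,
                            conflictAmplitudeUv = 0, motorAmplitudeUv = 0)
    sub <- simulateSubject(cfg, "S01")
    ep <- segmentEpochs(sub$recording, correctOnly = FALSE)
    side <- stimulusSide(sub$recording@events$hand,
                         sub$recording@events$conflict)
    sel <- epochTimes(ep) >= 190 & epochTimes(ep) <= 250
    po <- match(c("PO9", "PO10"), channelNames(ep))
    feat <- rowMeans(epochData(ep)[, po[1], sel]) -
      rowMeans(epochData(ep)[, po[2], sel])
    abs(mean(feat[side == "left"]) - mean(feat[side == "right"])) /
      (sd(feat) + 1e-12)
  }, 0)
  expect_true(all(diff(sep) >= -1e-9))
  expect_gt(sep[3], sep[1])
})

test_that("cohorts pool events and behavior deterministically", {
  cfg <- simulationConfig(nTrials = 8, nChannels = 8, sfreq = 100, seed = 5)
  coh <- simulateCohort(3, cfg)
  expect_length(coh$recordings, 3)
  expect_equal(nrow(coh$behavior), 24)
  coh2 <- simulateCohort(3, cfg)
  expect_identical(coh$recordings[["S02"]]@data, coh2$recordings[["S02"]]@data)
  expect_error(simulateCohort(1, cfg), "at least 2")
})
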