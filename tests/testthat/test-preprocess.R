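# Filtering, segmentation, artifact criteria, baseline and crop.

# a bare recording around a given data matrix
wrapRecording <- function(data, sfreq = 500, events = NULL, nChannels = 8) {
  m <- makeMontage(nChannels)
  if (is.null(events))
    events <- data.frame(onset_sample = integer(), hand = character(),
                         conflict = character(), correct = logical(),
                         rt_ms = numeric())
  new("ContinuousRecording", subjectId = "T", sfreq = sfreq, data = data,
      events = events, montage = m, metadata = list())
}

test_that("band-pass magnitude response: stop-band, pass-band and DC", {
  # long signal: the 0.5 Hz high-pass has ~1 s edge transients (both ends
  # under filtfilt), so judge the steady state in the middle of 24 s
  sfreq <- 500
  t <- seq(0, 24, by = 1 / sfreq)[-1]
  mk <- function(f) sin(2 * pi * f * t)
  rms <- function(x) sqrt(mean(x^2))
  mid <- seq(round(length(t) * .4), round(length(t) * .6))  # skip edges
  x <- rbind(mk(40), mk(10), rep(1, length(t)),
             matrix(0, 5, length(t)))
  rec <- wrapRecording(x, sfreq)
  out <- bandpassFilter(rec, 0.5, 20)@data
  att40 <- 20 * log10(rms(out[1, mid]) / rms(x[1, mid]))
  expect_lt(att40, -24)  # one octave above the 20 Hz edge
  att10 <- 20 * log10(rms(out[2, mid]) / rms(x[2, mid]))
  expect_gt(att10, -1)   # pass band essentially untouched
  expect_lt(max(abs(out[3, mid])), 1e-3)  # DC removed
})

test_that("the filter's slope near the high edge approaches 48 dB/octave", {
  # measured from the impulse response of the full cascade
  sfreq <- 500
  imp <- matrix(0, 8, 2^13); imp[, 2^12] <- 1
  h <- bandpassFilter(wrapRecording(imp, sfreq), 0.5, 20)@data[1, ]
  H <- abs(fft(h))
  freqs <- (seq_along(H) - 1) * sfreq / length(H)
  at <- function(f) 20 * log10(H[which.min(abs(freqs[1:(length(H) / 2)] - f))])
  slope <- at(40) - at(80)  # dB lost over one octave in the stop band
  expect_gt(slope, 40)
  expect_lt(slope, 60)
})

test_that("segmentation yields 800-sample epochs at 500 Hz and honors correctness", {
  sfreq <- 500
  on <- c(1000, 3000, 5000)
  ev <- data.frame(onset_sample = on, hand = c("left", "right", "left"),
                   conflict = c("conflict", "nonconflict", "nonconflict"),
                   correct = c(TRUE, FALSE, TRUE), rt_ms = c(400, 380, 420))
  rec <- wrapRecording(matrix(rnorm(8 * 6000), 8), sfreq, ev)
  ep <- segmentEpochs(rec)
  expect_equal(nTimepoints(ep), 800)           # 1600 ms
  expect_equal(nTrials(ep), 2)                 # correct only
  expect_equal(epochTimes(ep)[1], -100)
  ep2 <- segmentEpochs(rec, correctOnly = FALSE)
  expect_equal(nTrials(ep2), 3)
  # correct_only = FALSE on all-correct data changes nothing
  rec2 <- rec; rec2@events$correct <- TRUE
  expect_equal(epochData(segmentEpochs(rec2)),
               epochData(segmentEpochs(rec2, correctOnly = FALSE)))
  # event too close to the recording edge is dropped with a warning
  ev3 <- rbind(ev, data.frame(onset_sample = 5990, hand = "left",
                              conflict = "conflict", correct = TRUE,
                              rt_ms = 400))
  rec3 <- wrapRecording(matrix(rnorm(8 * 6000), 8), sfreq, ev3)
  expect_warning(ep3 <- segmentEpochs(rec3), "dropped")
  expect_equal(nTrials(ep3), 2)
})

test_that("artifact criteria flag steps, range excursions and flat channels", {
  ep <- makeTestEpochs(nTrials = 5, nChannels = 8, nTimepoints = 400,
                       sfreq = 500, seed = 8)
  ep@data <- ep@data * 5                       # ~5 uV noise, comfortably clean
  ep@data[2, 3, 200] <- ep@data[2, 3, 199] + 300  # single 300 uV jump
  ep@data[4, 5, ] <- 0                          # dead channel
  out <- rejectArtifacts(ep)
  expect_equal(out$log$kept, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_true(out$log$step[2] && out$log$range[2])  # exceeds both bounds
  expect_true(out$log$flat[4])
  expect_equal(nTrials(out$epochs), 3)
  expect_equal(as.character(epochLabels(out$epochs)),
               as.character(epochLabels(ep))[c(1, 3, 5)])
})

test_that("rejection is monotone in its thresholds", {
  ep <- makeTestEpochs(nTrials = 30, nChannels = 8, nTimepoints = 300,
                       sfreq = 500, seed = 21)
  ep@data <- ep@data * 40  # large noise so criteria actually bind
  kept <- function(stepThr, rangeThr, flatThr)
    sum(rejectArtifacts(ep, stepUvPerMs = stepThr, rangeUv = rangeThr,
                        flatUv = flatThr)$log$kept)
  base <- kept(50, 200, 0.5)
  expect_lte(kept(10, 200, 0.5), base)   # stricter step
  expect_lte(kept(50, 100, 0.5), base)   # stricter range
  expect_lte(kept(50, 200, 5), base)     # stricter (raised) flat threshold
})

test_that("baseline correction zeroes the window mean and is idempotent", {
  ep <- makeTestEpochs(nTrials = 6, nChannels = 8, nTimepoints = 200,
                       sfreq = 500, seed = 3)
  ep@timeMs <- ep@timeMs - 100  # -100 .. 298 ms
  b1 <- baselineCorrect(ep)
  sel <- b1@timeMs >= -100 & b1@timeMs < 0
  expect_lt(max(abs(apply(epochData(b1)[, , sel], c(1, 2), mean))), 1e-9)
  b2 <- baselineCorrect(b1)
  expect_equal(epochData(b2), epochData(b1), tolerance = 1e-12)
  # constant-offset epochs become all-zero
  ep@data[] <- 7.5
  expect_lt(max(abs(epochData(baselineCorrect(ep)))), 1e-12)
})

test_that("cropping to the decoding window keeps 750 of 800 samples", {
  ep <- makeTestEpochs(nTrials = 3, nChannels = 8, nTimepoints = 800,
                       sfreq = 500, seed = 5)
  ep@timeMs <- seq(-100, by = 2, length.out = 800)
  cr <- cropForModel(ep)
  expect_equal(nTimepoints(cr), 750)
  expect_equal(cr@timeMs[1], 0)
  expect_equal(epochData(cropForModel(cr)), epochData(cr))  # idempotent
  expect_error(cropForModel(ep, 100, 100), "empty")
  expect_error(cropForModel(ep, 2000, 2100), "outside")
})
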