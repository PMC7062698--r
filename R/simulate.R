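# Synthetic Simon-task EEG generator.
#
# Each subject is a continuous 1/f-noise recording with stimulus events and
# three planted, class-informative components:
#   * a stimulus-side-lateralized parieto-occipital negativity at 190-250 ms
#     (N1-like attentional component, larger contralateral to the stimulus),
#   * a fronto-central negativity at 300-400 ms scaled up on conflict trials
#     (conflict-monitoring component),
#   * a response-hand-lateralized central motor component preceding the
#     button press.
# Waveforms are Gaussian-windowed half-sine bumps peaking at the window
# center; the background is synthesized in the frequency domain with a 1/f
# amplitude spectrum and spatially mixed by a distance-decay kernel on the
# montage sphere. Behavior (lognormal RTs, Bernoulli errors) carries the
# Simon effect and the hand-by-conflict interaction of the emulated task.

#' Simulation configuration
#'
#' See [SimulationConfig-class] for slot meanings. Defaults encode the task
#' (400 trials, 2000-2500 ms response-stimulus interval, 500 Hz, 60 channels)
#' and the reported behavioral means; component amplitudes are generator
#' parameters with moderate single-trial signal-to-noise defaults.
#'
#' @param nTrials,rsiRangeMs,sfreq,nChannels task structure.
#' @param n1AmplitudeUv,n1WindowMs,conflictAmplitudeUv,conflictWindowMs,motorAmplitudeUv
#'   planted component amplitudes (microvolts) and windows (ms).
#' @param noiseScaleUv background standard deviation, microvolts.
#' @param rtNonconflictMs,rtConflictMs,errNonconflict,errConflict behavioral
#'   condition means.
#' @param seed master seed.
#' @return A [SimulationConfig-class].
#' @export
#' @examples
#' cfg <- simulationConfig(nTrials = 40, seed = 7)
simulationConfig <- function(nTrials = 400L, rsiRangeMs = c(2000, 2500),
                             n1AmplitudeUv = 6, n1WindowMs = c(190, 250),
                             conflictAmplitudeUv = 5,
                             conflictWindowMs = c(300, 400),
                             motorAmplitudeUv = 5, noiseScaleUv = 10,
                             rtNonconflictMs = 393, rtConflictMs = 430,
                             errNonconflict = 0.034, errConflict = 0.096,
                             sfreq = 500, nChannels = 60L, seed = 1L) {
  new("SimulationConfig", nTrials = as.integer(nTrials),
      rsiRangeMs = rsiRangeMs, n1AmplitudeUv = n1AmplitudeUv,
      n1WindowMs = n1WindowMs, conflictAmplitudeUv = conflictAmplitudeUv,
      conflictWindowMs = conflictWindowMs, motorAmplitudeUv = motorAmplitudeUv,
      noiseScaleUv = noiseScaleUv, rtNonconflictMs = rtNonconflictMs,
      rtConflictMs = rtConflictMs, errNonconflict = errNonconflict,
      errConflict = errConflict, sfreq = sfreq,
      nChannels = as.integer(nChannels), seed = as.integer(seed))
}

# deterministic 31-bit seed derived from a base seed and a string key
deriveSeed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (v in utf8ToInt(as.character(key))) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

# Gaussian-windowed half-sine bump, peak 1 at the window center
.bump <- function(tMs, fromMs, toMs) {
  out <- numeric(length(tMs))
  inw <- tMs >= fromMs & tMs <= toMs
  tc <- (fromMs + toMs) / 2
  sg <- (toMs - fromMs) / 4
  out[inw] <- sin(pi * (tMs[inw] - fromMs) / (toMs - fromMs)) *
    exp(-0.5 * ((tMs[inw] - tc) / sg)^2)
  out
}

# 1/f-amplitude background noise, spatially mixed on the montage sphere.
# Synthesized at the next highly composite length (mixed-radix FFTs are
# O(n log n) only for smooth n) and truncated.
.backgroundNoise <- function(montage, nSamples, sfreq, scaleUv) {
  C <- nChannels(montage)
  if (scaleUv == 0) return(matrix(0, C, nSamples))
  n <- stats::nextn(nSamples, c(2, 3, 5))
  freqs <- seq(0, sfreq / 2, length.out = n %/% 2 + 1)
  amp <- 1 / pmax(freqs, 1)  # flat below 1 Hz, 1/f above
  amp[1] <- 0                # no DC
  g <- matrix(0, C, nSamples)
  for (ch in seq_len(C)) {
    ph <- runif(length(amp), 0, 2 * pi)
    spec <- amp * exp(1i * ph)
    full <- c(spec, Conj(rev(spec[2:(n - length(spec) + 1)])))
    x <- Re(fft(full, inverse = TRUE))
    g[ch, ] <- x[seq_len(nSamples)] / sd(x)
  }
  # distance-decay spatial mixing; unit-norm rows preserve channel variance
  p <- channelPositions(montage)
  d2 <- outer(rowSums(p^2), rowSums(p^2), "+") - 2 * tcrossprod(p)
  K <- exp(-pmax(d2, 0) / (2 * 0.4^2))
  K <- K / sqrt(rowSums(K^2))
  scaleUv * (K %*% g)
}

# per-cell behavioral means mirroring the hand-by-conflict structure of the
# emulated task (non-conflict: right hand faster/more accurate; conflict:
# interaction reverses the error pattern)
.cellMeans <- function(config) {
  rtn <- config@rtNonconflictMs; rtc <- config@rtConflictMs
  en <- config@errNonconflict;  ec <- config@errConflict
  list(
    rt = c(left_nonconflict = rtn + 4.5, right_nonconflict = rtn - 4.5,
           left_conflict = rtc + 1, right_conflict = rtc - 1),
    err = c(left_nonconflict = min(1, en + 0.004),
            right_nonconflict = max(0, en - 0.004),
            left_conflict = max(0, ec - 0.010),
            right_conflict = min(1, ec + 0.010)))
}

.componentChannels <- function(montage) {
  ch <- channelNames(montage)
  pick <- function(want, w) {
    keep <- want %in% ch
    list(channels = want[keep], weights = w[keep])
  }
  list(
    n1Left  = pick(c("PO9", "PO7", "O1", "PO3"), c(1, 0.6, 0.5, 0.3)),
    n1Right = pick(c("PO10", "PO8", "O2", "PO4"), c(1, 0.6, 0.5, 0.3)),
    conflict = pick(c("FC1", "FCz", "Fz", "F8", "FC2", "Cz"),
                    c(1, 0.8, 0.6, 0.5, 0.6, 0.4)),
    motorLeft  = pick(c("C3", "FC1", "CP1"), c(1, 0.5, 0.4)),
    motorRight = pick(c("C4", "FC2", "CP2"), c(1, 0.5, 0.4)))
}

#' Simulate one subject's Simon-task session
#'
#' Generates a continuous recording (1/f background plus planted components,
#' microvolts) with one event per trial and the trial-level behavior table.
#' Classes are balanced to within one trial. The planted component geometry
#' and windows are stored in the recording's `metadata$groundTruth` so that
#' downstream feature-localization claims can be scored against the truth.
#'
#' @param config a [SimulationConfig-class].
#' @param subjectIdent subject label; also individualizes the random stream.
#' @param rtShiftMs subject-level shift of both RT condition means, ms.
#' @param ampScale subject-level multiplier on all component amplitudes.
#' @return List with elements `recording` ([ContinuousRecording-class]) and
#'   `behavior` (data.frame: subject, hand, conflict, rt_ms, correct).
#' @export
#' @examples
#' sub <- simulateSubject(simulationConfig(nTrials = 12, nChannels = 16), "S01")
#' nrow(sub$behavior)
simulateSubject <- function(config, subjectIdent = "S01", rtShiftMs = 0,
                            ampScale = 1) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(deriveSeed(config@seed, subjectIdent))
  montage <- makeMontage(config@nChannels)
  sfreq <- config@sfreq
  n <- config@nTrials

  # balanced classes (within 1), shuffled
  base <- rep(trialClasses(), n %/% 4)
  extra <- trialClasses()[seq_len(n %% 4)]
  cls <- sample(c(base, extra))
  hand <- ifelse(grepl("^left", cls), "left", "right")
  conflict <- ifelse(grepl("conflict$", cls) & !grepl("nonconflict$", cls),
                     "conflict", "nonconflict")
  stimSide <- stimulusSide(hand, conflict)

  cm <- .cellMeans(config)
  rtMean <- cm$rt[cls] + rtShiftMs
  sdlog <- 0.2
  rt <- rlnorm(n, meanlog = log(pmax(rtMean, 50)) - sdlog^2 / 2, sdlog = sdlog)
  correct <- runif(n) >= cm$err[cls]

  rsi <- runif(n, config@rsiRangeMs[1], config@rsiRangeMs[2])
  gaps <- round((rt + rsi) / 1000 * sfreq)
  onsets <- cumsum(c(round(2 * sfreq), gaps[-n] ))
  nSamples <- onsets[n] + round(2 * sfreq)

  data <- .backgroundNoise(montage, nSamples, sfreq, config@noiseScaleUv)
  comp <- .componentChannels(montage)
  chIdx <- function(x) match(x$channels, channelNames(montage))

  addComponent <- function(trial, set, fromMs, toMs, amplitude) {
    if (length(set$channels) == 0 || amplitude == 0) return()
    s0 <- onsets[trial] + floor(fromMs / 1000 * sfreq)
    s1 <- onsets[trial] + ceiling(toMs / 1000 * sfreq)
    s0 <- max(1, s0); s1 <- min(nSamples, s1)
    tMs <- (seq(s0, s1) - onsets[trial]) * 1000 / sfreq
    wave <- .bump(tMs, fromMs, toMs) * amplitude
    idx <- chIdx(set)
    data[idx, s0:s1] <<- data[idx, s0:s1] + outer(set$weights, wave)
  }

  a <- ampScale
  for (i in seq_len(n)) {
    # N1: larger contralateral to the stimulus side, smaller ipsilateral
    contra <- if (stimSide[i] == "left") comp$n1Right else comp$n1Left
    ipsi <- if (stimSide[i] == "left") comp$n1Left else comp$n1Right
    addComponent(i, contra, config@n1WindowMs[1], config@n1WindowMs[2],
                 -a * config@n1AmplitudeUv)
    addComponent(i, ipsi, config@n1WindowMs[1], config@n1WindowMs[2],
                 -0.4 * a * config@n1AmplitudeUv)
    # fronto-central negativity, scaled up on conflict trials
    addComponent(i, comp$conflict, config@conflictWindowMs[1],
                 config@conflictWindowMs[2],
                 -a * config@conflictAmplitudeUv *
                   if (conflict[i] == "conflict") 1 else 0.3)
    # motor component contralateral to the responding hand, before the press
    mc <- if (hand[i] == "right") comp$motorLeft else comp$motorRight
    mi <- if (hand[i] == "right") comp$motorRight else comp$motorLeft
    addComponent(i, mc, rt[i] - 250, rt[i] + 50, -a * config@motorAmplitudeUv)
    addComponent(i, mi, rt[i] - 250, rt[i] + 50,
                 0.4 * a * config@motorAmplitudeUv)
  }

  medRt <- stats::median(rt)
  groundTruth <- list(
    n1 = list(channels = union(comp$n1Left$channels, comp$n1Right$channels),
              windowMs = config@n1WindowMs),
    conflict = list(channels = comp$conflict$channels,
                    windowMs = config@conflictWindowMs),
    motor = list(channels = union(comp$motorLeft$channels,
                                  comp$motorRight$channels),
                 windowMs = c(medRt - 250, medRt + 50)))

  events <- data.frame(onset_sample = onsets, hand = hand,
                       conflict = conflict, correct = correct, rt_ms = rt,
                       stringsAsFactors = FALSE)
  rec <- new("ContinuousRecording", subjectId = subjectIdent, sfreq = sfreq,
             data = data, events = events, montage = montage,
             metadata = list(groundTruth = groundTruth,
                             config = config, ampScale = ampScale))
  behavior <- data.frame(subject = subjectIdent, hand = hand,
                         conflict = conflict, rt_ms = rt, correct = correct,
                         stringsAsFactors = FALSE)
  list(recording = rec, behavior = behavior)
}

#' Simulate a cohort of Simon-task subjects
#'
#' Subject seeds derive deterministically from the master seed; subject-level
#' variation enters through a normal shift of the RT means and a lognormal
#' multiplier on the component amplitudes.
#'
#' @param nSubjects at least 2 (leave-one-subject-out is undefined below that).
#' @param config a [SimulationConfig-class]; the default is the desk-scale
#'   cohort configuration (200 trials per subject).
#' @param subjectRtSd between-subject SD of the RT shift, ms.
#' @param subjectAmpSd between-subject SD of `log(amplitude multiplier)`.
#' @return List with `recordings` (named list of [ContinuousRecording-class])
#'   and `behavior` (pooled data.frame).
#' @export
#' @examples
#' coh <- simulateCohort(2, simulationConfig(nTrials = 8, nChannels = 16))
#' names(coh$recordings)
simulateCohort <- function(nSubjects = 6,
                           config = simulationConfig(nTrials = 200L),
                           subjectRtSd = 20, subjectAmpSd = 0.15) {
  if (nSubjects < 2)
    stop("need at least 2 subjects for leave-one-subject-out evaluation")
  ids <- sprintf("S%02d", seq_len(nSubjects))
  set.seed(deriveSeed(config@seed, "cohort"))
  shifts <- rnorm(nSubjects, 0, subjectRtSd)
  scales <- exp(rnorm(nSubjects, 0, subjectAmpSd))
  recs <- vector("list", nSubjects); names(recs) <- ids
  beh <- vector("list", nSubjects)
  for (i in seq_len(nSubjects)) {
    sub <- simulateSubject(config, ids[i], rtShiftMs = shifts[i],
                           ampScale = scales[i])
    recs[[i]] <- sub$recording
    beh[[i]] <- sub$behavior
  }
  list(recordings = recs, behavior = do.call(rbind, beh))
}
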