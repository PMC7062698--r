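# Shared fixtures: tiny epoch sets built in code, a double-precision
# reference forward pass used as the independent oracle for the network, and
# a memoised desk-scale cohort run shared by the slower acceptance blocks.

# An EpochSet with given geometry filled with seeded Gaussian noise.
makeTestEpochs <- function(nTrials = 16, nChannels = 8, nTimepoints = 96,
                           sfreq = 100, seed = 1, labels = NULL,
                           subject = "T01") {
  set.seed(seed)
  if (is.null(labels))
    labels <- factor(rep(trialClasses(), length.out = nTrials),
                     levels = trialClasses())
  montage <- if (as.character(nChannels) %in% c("8", "16", "32", "60", "64")) {
    makeMontage(nChannels)
  } else {  # arbitrary prefix of the full cap, for geometry-only tests
    full <- makeMontage(64)
    new("Montage", channels = channelNames(full)[seq_len(nChannels)],
        positions = channelPositions(full)[seq_len(nChannels), , drop = FALSE])
  }
  data <- array(rnorm(nTrials * nChannels * nTimepoints),
                dim = c(nTrials, nChannels, nTimepoints))
  new("EpochSet", subjectId = subject, sfreq = sfreq, data = data,
      timeMs = seq(0, by = 1000 / sfreq, length.out = nTimepoints),
      labels = labels, montage = montage, csdApplied = FALSE,
      metadata = list())
}

# Independent double-precision forward pass of the network (inference mode):
# a from-scratch re-derivation of the architecture used to cross-check the
# single-precision engine and to supply finite-difference gradients.
refNetForward <- function(x, W, cfg) {
  C <- nrow(x); T <- ncol(x)
  F1 <- cfg@F1; D <- cfg@D; F2 <- cfg@F2
  K1 <- cfg@temporalKernel; K2 <- cfg@separableKernel
  eps <- 1e-3
  padL <- (K1 - 1) %/% 2
  xp <- cbind(matrix(0, C, padL), x, matrix(0, C, K1 - 1 - padL))
  Z1 <- array(0, c(F1, C, T))
  for (f in 1:F1) for (t in 1:T)
    Z1[f, , t] <- xp[, t:(t + K1 - 1), drop = FALSE] %*% W$W1[f, ]
  A1 <- Z1
  for (f in 1:F1)
    A1[f, , ] <- W$g1[f] * (Z1[f, , ] - W$rm1[f]) / sqrt(W$rv1[f] + eps) +
      W$b1[f]
  Z2 <- matrix(0, F2, T)
  for (f in 1:F1) for (d in 1:D)
    Z2[(f - 1) * D + d, ] <- t(A1[f, , ]) %*% W$Wd[(f - 1) * D + d, ]
  B2 <- (Z2 - W$rm2) / sqrt(W$rv2 + eps) * W$g2 + W$b2
  E2 <- ifelse(B2 > 0, B2, expm1(B2))
  T1 <- T %/% 4
  P1 <- vapply(1:T1, function(u)
    rowMeans(E2[, ((u - 1) * 4 + 1):(u * 4), drop = FALSE]), numeric(F2))
  P1 <- matrix(P1, nrow = F2)
  padL2 <- (K2 - 1) %/% 2
  Pp <- cbind(matrix(0, F2, padL2), P1, matrix(0, F2, K2 - 1 - padL2))
  S <- matrix(0, F2, T1)
  for (j in 1:F2) for (u in 1:T1)
    S[j, u] <- sum(W$Wsd[j, ] * Pp[j, u:(u + K2 - 1)])
  Q <- W$Wsp %*% S
  B3 <- (Q - W$rm3) / sqrt(W$rv3 + eps) * W$g3 + W$b3
  E3 <- ifelse(B3 > 0, B3, expm1(B3))
  T2 <- T1 %/% 8
  Fp <- vapply(1:T2, function(u)
    rowMeans(E3[, ((u - 1) * 8 + 1):(u * 8), drop = FALSE]), numeric(F2))
  Fp <- matrix(Fp, nrow = F2)
  as.vector(W$Wf %*% as.vector(t(Fp)) + W$bf)
}

# weights with non-trivial batch-norm statistics, to exercise those paths
refNetWeights <- function(model, seed = 2) {
  set.seed(seed)
  W <- model@weights
  F1 <- model@config@F1; F2 <- model@config@F2
  W$rm1 <- rnorm(F1, 0, 0.1); W$rv1 <- runif(F1, 0.5, 2)
  W$rm2 <- rnorm(F2, 0, 0.1); W$rv2 <- runif(F2, 0.5, 2)
  W$rm3 <- rnorm(F2, 0, 0.1); W$rv3 <- runif(F2, 0.5, 2)
  W$g1 <- runif(F1, 0.5, 1.5); W$b1 <- rnorm(F1, 0, 0.1)
  W$g2 <- runif(F2, 0.5, 1.5); W$b2 <- rnorm(F2, 0, 0.1)
  W$g3 <- runif(F2, 0.5, 1.5); W$b3 <- rnorm(F2, 0, 0.1)
  W
}

# ---------------------------------------------------------------------------
# Desk-scale parameter-recovery cohort (shared by the slower acceptance
# blocks): 6 subjects x 200 trials at the full 60-channel / 500 Hz geometry,
# high-SNR planted amplitudes, leave-one-subject-out with 2 validation
# subjects and 30 training epochs.

.acceptanceCache <- new.env(parent = emptyenv())

highSnrConfig <- function(seed = 11) {
  simulationConfig(nTrials = 200, n1AmplitudeUv = 15, conflictAmplitudeUv = 12,
                   motorAmplitudeUv = 12, noiseScaleUv = 10, seed = seed)
}

acceptanceCohortRun <- function() {
  if (!is.null(.acceptanceCache$run)) return(.acceptanceCache$run)
  coh <- simulateCohort(6, highSnrConfig())
  pp <- lapply(coh$recordings, preprocessRecording)
  eps <- lapply(pp, `[[`, "epochs")
  res <- runLoos(eps, netConfig(8, 2), nVal = 2, maxEpochs = 30, seed = 11,
                 returnModels = TRUE)
  .acceptanceCache$run <- list(cohort = coh, epochs = eps, result = res)
  .acceptanceCache$run
}
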