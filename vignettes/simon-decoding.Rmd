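---
title: "Decoding hand and conflict from single-trial Simon-task EEG"
author: "eegconflict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding hand and conflict from single-trial Simon-task EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegconflict)
```

## The problem

In the Simon task, a lateralized target stimulus instructs a left- or
right-hand response; when stimulus side and responding hand mismatch
(conflict trials), responses are slower and more error-prone. The classical
electrophysiological account attributes this cost to attentional selection
(an occipito-parietal N1-like component around 190–250 ms, lateralized with
respect to the attended stimulus) and to conflict monitoring / response
selection (a fronto-central negativity around 300–400 ms, together with
hand-lateralized motor activity).

This package implements a single-trial decoding pipeline around that
paradigm: every trial is classified into one of four classes — left hand
non-conflict, left hand conflict, right hand non-conflict, right hand
conflict — directly from the preprocessed EEG, by a compact convolutional
network. Per-subject significance is assessed against a binomial
chance-level threshold, and the trained models are interrogated with
gradient saliency maps to ask *which* channels and time points carry the
decision. Because no public dataset accompanies the paradigm, the package
ships a synthetic-cohort generator with known ground truth, so every stage —
preprocessing, decoding, significance, and feature localization — is
testable end to end.

## The decoding model

The classifier is a compact two-block convolutional network for
channels-by-time input:

* **Block 1**: a temporal convolution (`F1` filters of width 64 samples,
  same padding, linear) learns band-limited temporal filters; a depthwise
  spatial convolution spanning all `C` channels learns `D` spatial filters
  per temporal map (no bias — each convolution is followed by batch
  normalization); ELU activation; average pooling over 4 samples; dropout.
* **Block 2**: a separable convolution (depthwise temporal width 16, then a
  pointwise 1×1 mixing to `F2 = F1 * D` maps), batch norm, ELU, average
  pooling over 8 samples, dropout, and a dense softmax over the four
  classes.

With the default `(F1, D) = (8, 2)`, 60 channels and 750 input samples, the
network has 3,540 trainable parameters (the depthwise layer alone accounts
for `C * D * F1 = 960`); pooling uses non-overlapping windows with floor
division, so 750 samples become 187 and then 23, and the flatten length is
`16 * 23 = 368`. The two candidate configurations, `(4, 2)` and `(8, 2)`,
can be compared with `selectFilterConfig()`.

Training minimizes a class-weighted cross-entropy (weight = inverse class
proportion, majority class weight exactly 1, implemented as per-sample loss
scaling) with ADAM (learning rate 1e-3, default moments), batch size 32,
for up to 500 epochs; after every epoch the unweighted validation
cross-entropy is recorded and the returned model is the checkpoint with the
minimum validation loss. Dropout probability is 0.25 and max-norm
constraints of 1.0 (depthwise spatial filters) and 0.25 (incoming dense
weights per class) are applied after every update; batch normalization uses
epsilon 1e-3 and running-average momentum 0.99. These regularization
constants follow the reference design of compact EEG decoders for
cross-subject use. The engine is implemented in single-precision C++
(hand-vectorized kernels with a portable scalar fallback) so that a full
leave-one-subject-out run fits on one CPU; for a fixed seed, shuffling,
dropout and therefore whole training runs are exactly reproducible.

## Evaluation protocol

Decoding is evaluated with leave-one-subject-out (LOOS) cross-validation:
each subject serves once as the test set, a fixed number of validation
subjects (`nVal`) is drawn at random from the remainder per split (seeded),
and the rest train the model. The test-set size therefore equals the number
of trials the held-out subject contributes.

Chance level for a 4-class problem is 25% only asymptotically; for a finite
test set of size $n$ the significance boundary is taken from the binomial
inverse CDF,

$$\mathrm{threshold}(\alpha) = \mathrm{binoinv}(1 - \alpha,\, n,\, 1/c) \cdot \frac{100}{n},$$

and a subject counts as decodable when accuracy strictly exceeds this
threshold (`chanceThreshold()`; $\alpha = 0.05$, $c = 4$). For $n \approx
346$ trials the threshold is about 28.9%, and it approaches 25% as $n$
grows. Permutation testing is deliberately not implemented: with hundreds
of trials per test set the binomial boundary is equivalent and does not
require re-estimating the network.

The cohort summary reports mean accuracy, the number and fraction of
above-chance subjects, the mean accuracy-minus-threshold margin with a
two-sided one-sample t statistic over the above-chance subjects
(descriptive, mirroring the usual reporting style), and a trial-weighted,
row-normalized pooled confusion matrix (pooling across subjects is
trial-weighted; a subject-averaged alternative would weight small test sets
up, which we judged less faithful to a pooled-count reading).

The same splits drive the SVM comparison (`runSvmLoos()`): an RBF-kernel
SVM with grid search over `C = {0.01, 0.1, 1, 10, 100}` and `gamma = {0.1,
…, 0.9, 1, 2, …, 10}` on the validation subjects (the gamma grid steps by
0.1 up to 1 and by 1 up to 10). The feature representation — flattened,
per-feature standardized, time-decimated epochs with statistics fitted on
the training split only — is this package's own choice of a deliberately
simple baseline representation. Multi-class handling is one-vs-one with
majority voting.

## Preprocessing

`preprocessRecording()` fixes the canonical order: band-pass filter →
segmentation → artifact rejection → current source density → baseline →
crop.

* **Filter**: 0.5–20 Hz. Implemented as order-4 Butterworth high- and
  low-pass sections applied forward-backward (`signal::filtfilt`): one pass
  gives 24 dB/octave, the squared magnitude of the zero-phase application
  yields the target ≈48 dB/octave roll-off.
* **Segmentation**: −100 to 1500 ms around stimulus onset (1600 ms, 800
  samples at 500 Hz), correct trials only.
* **Artifact rejection**: an epoch is dropped when, on any channel, a
  voltage step exceeds 50 µV/ms, the max–min range within any 200 ms window
  exceeds 200 µV, or some channel stays below 0.5 µV peak-to-peak in every
  100 ms window. Criterion windows slide sample by sample — the strictest,
  fully deterministic reading, since tiled windows would depend on an
  arbitrary phase. (Lowering the step/range thresholds or raising the flat
  threshold can only shrink the kept set; the tests assert this
  monotonicity.)
* **Current source density**: spherical-spline surface Laplacian with
  stiffness `m = 4`, regularization `lambda = 1e-5` and 50 Legendre terms —
  the canonical defaults of the CSD literature — scaled by a 10 cm head
  radius to µV/cm². The transform is
  linear and reference-free (a constant added to all channels maps to 0).
* **Baseline**: mean over −100–0 ms subtracted per trial and channel, as
  the final step before cropping — i.e. *after* CSD, so the baseline is
  defined in the same (current-density) units the model sees.
* **Crop**: 0–1500 ms (750 samples at 500 Hz) feed the model.

ICA-based ocular correction and flat-channel interpolation are out of scope:
the synthetic data carries neither ocular components nor dead channels by
default (a dead channel can be injected to exercise the flat criterion).

## The synthetic cohort generator

`simulateCohort()` produces what the pipeline needs and nothing more: a
continuous 60-channel, 500 Hz recording per subject with stimulus events at
response–stimulus intervals of 2000–2500 ms, and a trial-level behavior
table.

Three class-informative components are planted per trial, all
Gaussian-windowed half-sine bumps (smooth, band-limited inside the 0.5–20 Hz
band, analytically controllable, peak at the window center):

* an N1-like parieto-occipital negativity at 190–250 ms, larger
  contralateral to the stimulus side (PO9/PO7/O1/PO3 vs PO10/PO8/O2/PO4,
  ipsilateral at 40% amplitude);
* a fronto-central negativity at 300–400 ms (FC1, FCz, Fz, F8, FC2, Cz) at
  full amplitude on conflict trials and 30% on non-conflict trials
  (conflict monitoring is present but weaker without conflict);
* a motor component contralateral to the responding hand (C3/C4 with
  fronto-central and centro-parietal neighbors), from 250 ms before to
  50 ms after the button press, with an ipsilateral positive counterpart at
  40% — a lateralized-readiness-style asymmetry.

The background is synthesized in the frequency domain with a 1/f amplitude
spectrum (flattened below 1 Hz, no DC) and mixed across channels by a
Gaussian distance-decay kernel on the montage sphere with unit-norm rows —
spatially correlated, EEG-like statistics without head modelling. Behavior
uses lognormal RTs (sdlog 0.2) around per-cell means derived from the
emulated task's cell structure (conflict cost ≈37 ms, a ≈5 ms hand effect
and a hand×conflict interaction; error rates 3.4%/9.6% with the interaction
reversing the hand pattern under conflict), and Bernoulli errors. Misses
are not simulated: error trials exist to exercise the correct-only filter,
and every trial has a response. Subject-level variation enters as a normal
RT shift (SD 20 ms) and a lognormal amplitude multiplier (SD 0.15).

Because single-trial component amplitudes and SNR are not quantified
anywhere we could anchor them, the amplitude defaults (6/5/5 µV on a 10 µV
1/f background) are a deliberate middle ground: decodable but not trivial.
The test suite's parameter-recovery cohort uses a high-SNR setting
(15/12/12 µV) chosen so that decoding is clearly above chance at desk
scale, which is what that test is for. What passing those tests shows is
that the pipeline recovers planted structure through the full preprocessing
and training chain; it does not certify performance on real EEG, whose
artifacts, non-stationarities and component variability the generator
deliberately does not model.

## Saliency maps

`trialSaliency()` differentiates the *pre-softmax* score of a class with
respect to the input (softmax gradients saturate and mix classes). The
per-trial map is the elementwise absolute gradient; `classAverageSaliency()`
averages the maps of all trials of a class — each trial attributed to its
own true class — and min–max normalizes the average to [0, 1] (a constant
averaged map is reported as degenerate rather than divided by zero).
Rectification before averaging is the default, following the convention of
the gradient-saliency method (signed averaging is available via
`rectify = FALSE`; sign conventions cancel class-consistent polarity and
tend to wash out). Gradients are evaluated in inference mode: dropout off,
running batch-norm statistics, so the map describes the deployed
classifier. Cohort-level maps average subject maps with equal weight.

`featureRanking()` reduces a map to ranked contiguous high-saliency
clusters, and `saliencyLocalization()` scores a map against the generator's
planted ground truth (share of top-5% saliency mass inside the planted
channel-window cells, and whether the global maximum falls inside).

Two properties of the pipeline bound how concentrated that score can be.
The surface Laplacian has a center–surround spatial kernel: a component
injected at a few electrodes appears, in the CSD representation the model
actually sees, at those electrodes *and* with opposite sign at their
neighbors — on the planted cohorts the "excess" saliency mass sits
precisely at P7/P8 beside the planted parieto-occipital set and at C1/C2
beside the planted central set. Likewise the 64-sample (128 ms at 500 Hz)
temporal kernel gives every input sample a receptive field that extends
attribution beyond the planted windows. On the desk-scale planted cohort
the top-5% mass share inside the *literal* injection cells is therefore
around 0.22–0.27 — a 7–9-fold enrichment over the 0.03 expected under
spatially uniform mass, with the global maximum inside the planted cells
for every class, but far from total concentration. Rectified and signed
averaging give the same picture (the spread is systematic, not a noise
floor). Localization scores against literal injection cells should be read
with this in mind.

## Behavioral statistics

`rmAnova2x2()` computes the 2×2 within-subject ANOVA (hand × conflict) from
per-subject contrast scores: each 1-df effect is a paired t on its
contrast, `F = t²` with df (1, n−1), and partial η² = SS_effect /
(SS_effect + SS_error) = F / (F + n − 1). With single-df effects a
sphericity correction is vacuous, so none is applied. Post-hoc paired
t-tests (`pairedT()`) are reported uncorrected, matching the field's
reporting style for this design; a Bonferroni adjustment is a one-liner on
the returned p values if desired. The tests verify the implementation
against both a direct sums-of-squares decomposition and `aov()` with
within-subject error strata.

## Numerical and design notes

* Single precision in the network engine: weights are ~3.5k parameters and
  EEG amplitudes are O(10) µV after CSD scaling; float rounding is far
  below the Monte-Carlo variation of training. The independent
  double-precision reference implementation in the test suite agrees with
  the engine's forward pass to ~1e-6 relative, and analytic input gradients
  match central finite differences of that reference to well under 1e-3.
* "Same" padding for even kernels pads one sample more on the right
  (64 → 31 left / 32 right), the usual convention of the reference
  implementations.
* Pooling truncates (floor division): trailing samples that do not fill a
  window are discarded, so T = 750 → 187 → 23.
* Ties in the SVM grid search resolve to the smallest `C`, then the
  smallest `gamma`; ties in `selectFilterConfig()` to the larger `F1`.
* All randomness is derived from user-visible seeds: per-subject simulation
  seeds, per-split validation draws and per-split training seeds come from
  a deterministic hash of the master seed, so cohorts and whole evaluations
  are bit-reproducible; the SVM and the network consume byte-identical
  splits for the same seed.
* Epoch containers persist as TSV matrices with a JSON attribute sidecar
  (subject, sampling rate, labels, time axis, montage) — plain-text,
  diff-able, dependency-free.

## Problem sizes used by the test suite

The suite exercises the full method at desk scale, chosen a priori as the
smallest sizes that make the scientific claims testable:

* parameter recovery: 6 subjects × 200 trials at the full 60-channel /
  500 Hz geometry, LOOS with 2 validation subjects (with 6 subjects, 4
  validation subjects would leave a single training subject), 30 training
  epochs at batch 32 — the validation-loss trend of this architecture
  flattens after roughly 20 epochs, so 30 is comfortably past it;
* type-I calibration: 40 null subject-folds (10 independent 4-subject
  cohorts × 80 trials, 16 channels, 1 validation subject, 3 epochs) with
  all planted amplitudes zero — under the null the decoder is at chance
  regardless of montage size or training length, which is why these are
  scaled down hard;
* unit tests: 4–16 channel montages, 96–800 sample epochs, toy two-class
  problems that a linear classifier provably separates.

## Known limitations

* The generator's components are deterministic bumps plus stationary 1/f
  noise; real single-trial ERPs have latency jitter, amplitude fluctuations
  correlated with behavior, ocular/muscle artifacts and non-stationary
  spectra. Decoding accuracies obtained on synthetic cohorts say nothing
  quantitative about real-data accuracy.
* The spherical-spline CSD assumes exact unit-sphere electrode positions;
  no co-registration error model is included.
* Validation subjects are redrawn per split; a fixed validation set across
  splits would be an equally defensible protocol, and the choice only
  affects checkpoint-selection noise.
* Source localization (distributed inverse solutions) is out of scope; the
  saliency maps live in sensor space.
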