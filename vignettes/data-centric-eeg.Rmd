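---
title: "Data-centric curation for EEG emotion recognition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-centric curation for EEG emotion recognition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

EEG-based emotion recognition suffers from two chronic data problems:
labelled trials are scarce, and the nominal label of a trial (the emotion a
video clip was *meant* to elicit) is only as reliable as the participant's
actual emotional response. `eegcurate` implements a data-centric pipeline
around this observation: instead of deepening the classifier, it improves
the training data by (a) removing trials whose self-reported emotion
intensity is low — treating the self-report as a label-confidence proxy —
and (b) enlarging the training set with label-preserving synthetic trials.
A leakage-safe five-fold cross-validation harness measures the effect of
both levers on small 1-D convolutional classifiers.

The package works against SEED-VII-shaped data: 20 participants, 80 video
clips (12 per emotion for happy, sad, disgust, fear, surprise and anger,
plus 8 neutral clips), 62-channel EEG summarized per trial as a
310-dimensional differential-entropy (DE) feature vector — 62 channels
times 5 frequency bands, channel-major. The real dataset is
registration-gated; nothing here requires it. A seeded synthetic generator
reproduces the study's shape so every stage can be exercised and tested
offline.

## Differential-entropy features

For a Gaussian signal with variance $\sigma^2$, the differential entropy is
$h = \tfrac12\ln(2\pi e\,\sigma^2)$ nats. `extract_de_features()` follows
the SEED-family convention: each channel is band-pass filtered into delta
(1–4 Hz), theta (4–8), alpha (8–14), beta (14–31) and gamma (31–50 Hz),
split into non-overlapping 1-s windows, the Gaussian closed form is
evaluated on each window's unbiased sample variance (floored at $10^{-12}$
to keep degenerate windows finite), and windows are averaged — this
implements the "averaged over time" summary that collapses clips of
different lengths to a single vector per trial.

Numerical choices worth knowing:

* The band filter is a 4th-order Butterworth applied forward–backward
  (zero phase). The public `bandpass()` uses `signal::filtfilt()`. The
  batch path used for corpus-scale extraction applies the identical squared
  magnitude response in the frequency domain (one FFT per channel instead
  of ~600k filter calls per corpus); the two differ only in boundary
  handling and the suite pins their agreement on white noise.
* Band edges, window length (1 s) and the natural-log (nats) unit are
  package conventions, configurable via `band_spec()` and `window_s`; the
  dataset's own release does not document its exact settings.

## The synthetic study

`generate_corpus(gen_params())` builds the full 20 × 80 = 1600-trial study.
The generative model is deliberately simple enough that every downstream
stage has a closed-form anchor:

* For emotion $e$, a fixed template draw $u_{c,b,e} \sim N(0,1)$ sets the
  per-channel, per-band signal scale
  $\sigma_{c,b}(e) = \sigma_0 \exp(\kappa\, u_{c,b,e})$;
  participant $p$ multiplies all $\sigma$ by $\exp(s_p v_p)$,
  $v_p \sim N(0,1)$.
* Each band component is band-limited Gaussian noise at its $\sigma$,
  drawn directly on the band's FFT bins and summed across bands, so the
  population DE of every feature is known exactly
  (`template_de()`); extracted features deviate from it only through the
  Butterworth edge attenuation and the finite-window log bias, about 0.1
  nat in the narrow delta band and less elsewhere.
* A seeded, exact-count fraction `corrupt_frac` of trials is *corrupted*:
  their class-specific template component is shrunk toward the grand mean
  by `corrupt_attenuation` (0.2 by default — 80% of the class signal gone)
  and their self-report score is drawn from a low Beta distribution,
  `Beta(2, 12)`, instead of the engaged `Beta(8, 2)`. Scores therefore
  correlate with signal integrity by construction, mirroring the premise
  that a low self-report flags an unreliable trial.

Default effect sizes are chosen once, on a realism argument: per-feature
class effects in real DE features are tiny, and discriminability comes from
pooling hundreds of channels × bands. `class_effect = 0.012` (a ~1%
log-variance template effect per feature) reproduces that regime — a linear
classifier on clean data reaches high but not trivial subject-level
accuracy — and `participant_sd = 0.05` adds the common-mode
between-subject amplitude variation that makes subject-level splits
meaningfully harder than trial-level ones. The Beta score parameters put
~98% of engaged mass above 0.5 and ~94% of corrupted mass below 0.3.

What the generator does *not* emulate: real EEG spectra (1/f background,
artifacts), inter-channel covariance, non-stationarity, and — importantly —
*label* noise. Corruption attenuates a trial's class signal but never
relabels it, because every curation operator is required to be
label-preserving. Consequences of this are discussed under "Limitations".

## Curation: augment first, then clean

`apply_curation()` applies exactly one augmentation operator to the
training folds, then score-based cleaning to the union — so aggressive
cleaning also removes synthetic trials whose scores fall at or below the
threshold. Operators are never combined in one run.

* **Cleaning** (`clean_by_score`): keep trials with `score > tau`. The
  strict inequality means `tau = 0` still removes exact-zero scores, while
  `tau = NULL` disables filtering; the two are distinct configurations.
* **Averaging** (`augment_average`): element-wise means of `k = 5`
  same-emotion feature vectors. The group structure is a width-`k` sliding
  window (stride 1) over a seeded shuffle of the emotion's trials —
  "consecutive samples" in a randomized ordering — configurable to
  disjoint groups. Groups are formed within a single *emotion*, the finest
  label, so the operator is label-preserving under every task scheme. The
  synthetic score is the member mean, which is what the cleaning stage
  then sees.
* **Gaussian** (`augment_gaussian`): adds zero-mean feature noise at a
  nominal 15 dB SNR, scaled to each trial's signal power (mean square over
  the 310 features — well-defined even though DE values can be negative)
  and modulated per copy by $m \sim U(0.5, 1.5)$; output is exactly twice
  the input. Copies inherit label and score.
* **Time-domain** (`augment_time`): for two training participants who
  viewed the same clip, the raw signals are truncated to the shorter
  length, averaged sample-wise, and DE features are re-extracted. The
  synthetic score is the mean of the two self-reports. Averaging two
  independent signals halves the variance, so the result is *not* the mean
  of the two DE vectors — the suite asserts the two operators genuinely
  differ. Default pairing is one seeded perfect matching per clip (about
  half as many synthetics as training trials); `all_pairs` is opt-in.
  Pairs touching non-training participants are a hard error.

## Classifier

Three small 1-D CNN variants treat the feature vector as a length-310,
1-channel sequence: 64 conv filters of width 3 with ReLU, max-pool of
width 2, dropout, flatten, and either a direct output layer (variant 1,
dropout 0.5) or a dense-128 ReLU stage with dropout on both sides (0.25 in
variant 2, 0.5 in variant 3). The head is a single logistic unit for the
binary task and softmax otherwise, trained with Adam for 50 epochs at
learning rate $10^{-4}$ on the matching cross-entropy.

The trainer is implemented in the package (RcppArmadillo, single-precision
tensors with BLAS matrix products — the deep-learning convention). Choices
the protocol leaves open, declared here: batch size 32; Glorot-uniform
initialization; per-feature z-scoring with training-fold statistics
(applied identically with and without PCA); binary encoding HA = 1 with
ties at probability 0.5 going to the positive class; no validation split
during the 50 epochs. All randomness (initialization, shuffles, dropout)
derives from the seed, and identical seeds reproduce identical fits.

## Evaluation harness

`run_cv()` runs five folds. The default split is at the *subject* level
(whole participants per fold, 4 each at the default geometry), which is the
stricter reading of the protocol; a trial-level mode exists because the
study's description also admits that reading, and the discrepancy is
surfaced rather than hidden. Per fold: curate the training folds, fit the
optional PCA (retaining the smallest component count reaching 99%
cumulative variance) on curated training features only, standardize, train,
and evaluate on the *raw* test fold — never cleaned, never augmented, never
used for PCA or standardization fitting. In subject mode the union of
`source_participants` over all curated training trials must be disjoint
from the test participants; a violation aborts the run rather than
logging.

Metrics follow the standard confusion-matrix definitions; binary F1 scores
the high-arousal positive class (which is why binary F1 runs above
accuracy under the 75/25 class imbalance), multi-class F1 is
macro-averaged (the declared reading; micro/weighted are not reported).
Fold summaries use the sample (n−1) SD, the normal-approximation
half-width $1.96\,\mathrm{SD}/\sqrt{n}$ exactly as printed (not a
t-quantile), and two-sided paired t-tests across folds with a flagged
degenerate path for zero-variance differences.

Problem sizes used by the test suite and the acceptance script: the full
1600-trial corpus for the cleaning-threshold experiments (5 folds × 50
epochs per cell), and a 70-trial, 8-channel miniature of the same design
for structural checks — chosen so the complete suite exercises every path
at desk scale.

## Design decisions in the open

* **On-disk formats.** The canonical table is a plain CSV
  (`participant_id,clip_id,emotion,score,f_0001..f_0310`) with exact
  (`%.17g`) numbers, deterministic ordering and byte-stable rewrites. The
  container format is a single RDS file (R's native serialization) holding
  the full corpus including raw signals. The SEED-VII adapter reads a
  documented plain-text export of the gated dataset's DE features; it is
  optional and validated against a fixture, not against the gated files.
* **Synthetic provenance.** Synthetic trials carry `is_synthetic` and
  `source_participants`, which is what makes the leakage assertions
  enforceable after augmentation.
* **Exact-count corruption.** The corrupted subpopulation is a seeded
  sample of exactly `floor(corrupt_frac * n)` trials, so expected counts
  in tests are deterministic.
* **Rounding.** Reported improvements round half away from zero to one
  decimal, matching printed-table conventions.

## Limitations

* The corruption model is label-preserving by specification: corrupted
  trials lose most of their class signal but keep their (correct) clip
  label. Removing such trials discards little information a classifier
  was using, so the measured benefit of cleaning on this synthetic study
  is modest — run `scripts/acceptance.R` to see the computed gains. On
  real data the premise is stronger (a low self-report means the intended
  emotion was likely not felt at all, i.e. the label itself is suspect),
  and passing the synthetic recovery checks should not be read as a
  quantitative prediction for real EEG.
* The generator's stationary Gaussian signals make DE exactly the right
  feature; real EEG rewards DE only approximately.
* PCA neutrality is a real-data finding, not an architectural identity.
  The conv-over-features classifier shares its width-3 kernels across the
  310 feature positions; PCA rotates the features onto near-arbitrary axes
  (the synthetic covariance is close to diagonal plus one participant
  common mode), and a convolution is not rotation-invariant. On the
  synthetic study the PCA configuration therefore runs a few accuracy
  points below the plain one — the acceptance script reports the computed
  delta — and the effect persists if the features are standardized before
  the rotation, so it is the rotation, not variance truncation, that
  matters.
* Subject mode guards against participant leakage but, like the original
  protocol, shares video stimuli between train and test folds;
  clip-disjoint splits are out of scope.
* Accuracies reported on the synthetic study are not comparable to
  real-data numbers; reproducing those requires the gated dataset and is
  explicitly out of scope.
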