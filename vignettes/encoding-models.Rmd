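---
title: "Lagged encoding models of high-frequency-band iEEG from facial-emotion features"
author: "hfbEncode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lagged encoding models of high-frequency-band iEEG from facial-emotion features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfbEncode)
```

## The problem

During naturalistic movie watching, the facial expressions on screen can be
described continuously by a bank of emotion scores (48 bounded features such
as *joy*, *guilt* or *embarrassment*, one value per video frame). Intracranial
EEG recorded at the same time provides, per electrode contact, a
high-frequency-band (HFB, 110–140 Hz) amplitude trace that is commonly read
as a proxy for local population firing. The question this package
operationalizes is: **how well do time-lagged emotion features linearly
predict the HFB response of a cortical region**, how does that accuracy
differ between regions (dorsolateral prefrontal cortex, DLPFC, versus
posterior superior temporal cortex, pSTC), between stimulus conditions
(speech versus music blocks), and between age groups — and **which features
carry the weight**, in particular the self-conscious "complex" emotions
(guilt, embarrassment, pride, envy) versus the six basic emotions.

## The model

For one subject, one region and one condition, let \(x_f(t)\) be emotion
feature \(f \in \{1..48\}\) at 2 Hz and \(y_c(t)\) the binned HFB response of
contact \(c\). The encoding model is ridge regression on lagged copies of
every feature,

\[
y_c(t) \;=\; b \;+\; \sum_{f} \sum_{\tau \in \{0,\,0.5,\,1\,\mathrm{s}\}}
w_{f\tau}\, x_f(t - \tau) \;+\; \varepsilon_c(t),
\]

with one weight vector \(w\) (144 entries) shared by all of the region's
contacts: the contacts' response rows are concatenated and the design matrix
is tiled once per contact. The penalty \(\alpha\|w\|^2\) leaves the intercept
unpenalized. Lags are causal — the stimulus at \(t-\tau\) predicts the
response at \(t\) — because the opposite direction has no physiological
reading for a sensory response.

Accuracy is estimated by fivefold cross-validation: rows are split into five
*contiguous temporal segments* (aligned across contacts), the model is fitted
on four and the Pearson correlation between predicted and measured held-out
responses is recorded; the reported accuracy is the mean of the five per-fold
r values. Contiguous (rather than random) folds limit leakage through
temporal autocorrelation. A single regularization coefficient is shared by
*all* (subject, region, condition) datasets: for each of 20 log-spaced
candidates between 10 and 10000 the cross-validated accuracy is computed on
every dataset with the same fold partitions, and the candidate maximizing
the unweighted mean is kept. Sharing one coefficient keeps the scale of the
weights comparable across subjects, which the weight-by-age analysis relies
on; per-fit feature standardization is deliberately *not* applied for the
same reason.

### Inference

Significance of a single fit uses a temporal-shuffle permutation test: the
rows of the condition's 2 Hz feature matrix are permuted jointly (all 48
features move together, preserving their instantaneous covariance), the
lagging–fitting–scoring pipeline is rerun at the same \(\alpha\) and fold
partition, and the observed mean r is compared with the null sample. The
two-tailed p-value uses absolute deviation from the null median with the
add-one Monte-Carlo correction, so \(p \ge 1/(n_{\mathrm{perm}}+1)\) and
\(p = 0\) cannot occur. \(\alpha\) is not re-selected inside permutations:
it is a study-level constant (and re-selection would multiply the cost by
the grid size). A circular-shift null is available as an option
(`perm_scheme = "circular"`).

Group-level contrasts are parametric: one-sample t against zero for a
group's accuracies, a paired t for speech-versus-music within subjects, and
a pooled-variance unpaired t for between-group contrasts (the pooled
convention is what yields df = 19 for groups of 8 and 13). The "voice
effect" is the per-subject difference \(\Delta r = r_{\mathrm{speech}} -
r_{\mathrm{music}}\), compared between groups with the unpaired test.

### Weight analysis

Per fitted cell, each feature's contribution is summarized as the mean of
\(|w_{f\tau}|\) over the three lags and five folds — the absolute value
deliberately ignores whether a feature maps to an HFB increase or decrease,
and averaging over lags and folds is the symmetric default (`reduce = "max"`
is available). Complex-emotion and basic-emotion group means average the
configured name lists; the complex list defaults to guilt, embarrassment,
pride and envy, with *interest* addable for the five-emotion grouping.
Subjects enter the weight-by-age analysis only if their permutation p is
below 0.05 (`filterIncluded()`). Pearson correlations of each feature's
weight with age are reported with uncorrected two-sided p values (a
Benjamini–Hochberg column is provided for convenience), and features are
ranked by r, ties broken by feature name so the ranking is deterministic.

## Signal processing

Raw multichannel recordings pass through, in order: a 50 Hz IIR notch
(quality factor 30, fundamental only), common-average re-referencing (good
channels define the reference; bad channels are excluded from the mean but
re-referenced), a fourth-order Butterworth band-pass at 110–140 Hz, the
analytic-signal (Hilbert) amplitude, epoching into 0–30 s block windows with
a 0.2 s pre-onset margin, anti-aliased downsampling to 400 Hz, a square-root
transform, and z-scoring per block and channel against the −0.2–0 s baseline
margin. The margin exists only for the baseline statistics; model fitting
uses the 0–30 s window binned into 500 ms means (60 bins per block).

Numerical choices worth knowing:

* **Zero-phase filtering.** All filters run forward–backward, doubling the
  effective order but keeping the envelope aligned with the stimulus. The
  filter-phase convention is not something the analysis should depend on,
  and zero phase is the only choice that keeps lags interpretable.
* **Resampling.** Rate conversion applies an eighth-order Butterworth
  low-pass at 0.8× the new Nyquist (zero-phase) and reads the trace off at
  the target grid; plain decimation would alias. A slow sinusoid survives a
  2048→400 Hz conversion with error below 1 %.
* **Analytic signal.** Computed by the standard FFT construction (double
  the positive frequencies, zero the negative ones).
* **Edges.** The first and last ~0.1 s of a filtered segment carry
  transients; closed-form checks in the tests exclude them.
* **Degenerate inputs.** A constant baseline (SD 0) is an error, as is a
  negative amplitude reaching the square root; a degenerate held-out fold
  (constant response) yields NaN, is dropped from the fold mean, and warns.
* **Ties.** The shared-\(\alpha\) argmax breaks ties toward the smaller
  coefficient; feature rankings break ties by name.

The bad-channel flagger (`flagBadChannels()`, > 1 % of samples beyond 8
robust SDs) stands in for visual artifact screening and is off by default.

## What the synthetic generator emulates — and what it does not

`simulateFeatures()` reproduces the stimulus geometry: 13 blocks of 30 s,
music on odd and speech on even positions (7 + 6), with the fifth music
block (overall block 9) face-free and excluded by default. Features are
smoothed Gaussian processes (correlation time ≈ 2 s) with sparse positive
bursts, squashed logistically into [0, 1] — bounded, skewed and
autocorrelated like real expression scores. `simulateResponse()` generates
binned responses from a known weight matrix with AR(1) noise (coefficient
0.3) scaled to a requested signal-to-noise variance ratio, so
contiguous-fold cross-validation is stressed by realistic serial
correlation. Ground-truth weights couple about half the features, each with
a signed amplitude spread over the three lags by a smooth positive profile,
because temporal response functions are sign-consistent and smooth across
neighbouring delays.

`simulateRaw()` synthesizes raw traces as pink background noise, a 50 Hz
line component, and a constant-amplitude carrier whose instantaneous
frequency wanders slowly inside 110–140 Hz, multiplied by the target
envelope. The constant-modulus carrier makes the target envelope exactly
the signal's envelope, so end-to-end tests have a well-defined ground
truth; real HFB amplitude additionally fluctuates stochastically, which the
generator represents through the envelope-level AR(1) noise term instead.

Two deliberate deviations from the original recording situation:

* **Inter-block gaps.** Synthetic blocks are separated by 1 s of
  stimulus-free signal (`standardEvents(gap = 1)`; `gap = 0` reproduces a
  contiguous film). With a contiguous stimulus the −0.2–0 s baseline falls
  on the preceding block's content, and its stimulus-driven envelope state
  — shared by all contacts — turns the per-block z-score into a random
  per-block offset and gain. That is a genuine property of pre-onset
  baselines in continuous films worth knowing about: in our end-to-end
  simulations it capped ground-truth weight recovery well below what
  block-demeaned refits achieve. A baseline protocol is statistically
  meaningful when the margin samples ongoing activity, so the generator's
  default does exactly that.
* **Binned-level cohorts.** `simulateCohort()` produces responses at the
  binned-HFB level (the generative counterpart of the fitted model) rather
  than synthesizing raw signals for every subject; raw synthesis is
  available per subject via `simulateSubject(level = "raw")`. Cohort-level
  statistical claims do not depend on the raw chain, which is exercised
  separately.

Passing tests on this generator therefore show that the pipeline recovers
what it assumes — linear lagged coupling with stationary noise — not that
real recordings satisfy those assumptions. Artifacts, epileptiform
activity, non-stationary arousal effects, audio-driven covariates and
correlated cross-contact noise are all absent from the generator.

## Default cohort and problem sizes

Simulated studies default to the observed group sizes: 8 childhood versus
13 post-childhood subjects for the DLPFC contrast (so the unpaired test has
df = 19) and 12 subjects for the weight-by-age analysis. Contacts per
region default to 6, mid-range of typical clinical regional coverage
(4–11); at least 4 contacts are required for a fit (`min_contacts`). The
weight-age generator uses per-entry complex-emotion coupling
\(0.1 + 0.02\,\mathrm{age}\) with jitter SD 0.1, and a signal-to-noise
ratio of 2 unless stated otherwise. The permutation-calibration simulation
runs 200 null datasets of 6 blocks × 12 features at 200 permutations each —
calibration of a proportion-based p-value does not depend on the dataset's
dimensions, and these sizes keep the whole suite fast. The end-to-end
checks fit one 12-retained-block subject (720 bins × 6 contacts stacked).

## Known limitations

* The permutation null destroys feature autocorrelation (shuffled rows are
  exchangeable); with strongly autocorrelated features and responses the
  shuffle null can be slightly liberal compared with a circular-shift null,
  which preserves each feature's autocorrelation and is available as
  `perm_scheme = "circular"`.
* The shared regularization coefficient is selected on the same
  cross-validation folds later used to report accuracy; with many datasets
  contributing, the per-dataset selection bias is small, but it is not zero.
* Weight summaries average per-fold weight vectors fitted on overlapping
  training sets; they are not independent replicates.
* The EDF reader supports the continuous, single-rate subset of the format
  (the common case for clinical exports), not EDF+D discontinuous files.
* Electrode localization, artifact rejection beyond the amplitude flagger,
  and any video analysis are out of scope: region labels and feature tables
  are inputs.
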