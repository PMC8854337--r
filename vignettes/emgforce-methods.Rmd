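---
title: "Methods: from surface EMG to knee-muscle force"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from surface EMG to knee-muscle force}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgforce)
```

## The problem

Surface EMG (sEMG) measures the electrical activity of contracting muscle
from skin electrodes. Under controlled, non-fatiguing conditions its
amplitude envelope tracks muscle activation, and activation drives force, so
a well-conditioned envelope is a usable proxy for the force a limb exerts.
This package implements an offline pipeline for the knee extensors — three
channels (vastus medialis, vastus lateralis, rectus femoris) plus a load-cell
force channel at 1 kHz — that (i) classifies each moment as active or rest
and (ii) estimates the continuous force trace from the EMG envelopes, with a
genetic algorithm for feature selection and hyper-parameter tuning and a
harness for the two usual evaluation protocols.

## The synthetic cohort

Real recordings of this kind are rarely shareable, so the package carries a
simulator (`simulate_recording()`, `generate_cohort()`) whose defaults *are*
the study conditions used throughout the tests: 5 s contraction / 5 s rest,
three repetitions per trial, two trials per subject, five subjects, 1 kHz
sampling.

The EMG model is the standard amplitude-modulation surrogate: each channel is
unit-RMS Gaussian noise band-limited to 20–450 Hz, multiplied by the
ground-truth activation (a trapezoid with 0.5 s ramps), plus the contaminants
the pre-processing chain exists to remove — a 50 Hz powerline sine (default
amplitude 20% of a unit peak envelope), a 5% DC offset, a slow (< 0.25 Hz)
baseline drift and white sensor noise. Force is a known smooth function of
activation: a 50 ms electromechanical lag, a power law (exponent 1.2), and
first-order dynamics with a 0.15 s time constant, scaled to the subject's
peak force and corrupted by load-cell noise. Per-subject parameters (channel
gains 0.6–1.2, peak force 150–300 N, noise amplitudes, exponent, lag) are
drawn once per subject from one master seed, so cohorts reproduce exactly.

What the simulator does *not* emulate — and hence what green tests do not
demonstrate about real data: motor-unit physiology (recruitment,
firing-rate modulation, crosstalk between channels), fatigue, electrode lift
or motion artifacts, and inter-day electrode placement variability. The
simulated classes are also cleaner than clinical data, which is why the
package's classification accuracies sit above the levels one should expect
in practice.

Two consequences of the force dynamics are worth noting. First, the force
*lags* the envelope, so a memoryless features-to-force map shows hysteresis
at contraction edges; the evaluation harness therefore aligns force targets
to the EMG by an electromechanical delay estimated per trial from the
cross-correlation of the channel-mean envelope with the force trace
(`estimate_delay()`, searched over 0–0.4 s — the physiological range plus
force-development time). Second, the exponential decay tails tie ranks
between activation plateaus, which caps the rank correlation between
activation and force near 0.88 even without noise; the tests assert the
tracking property through the Pearson correlation (≥ 0.95) instead.

## Pre-processing

EMG chain, in order: mean subtraction; 4th-order Butterworth band-pass
(20–500 Hz as configured, with the upper edge clamped to 0.45 × fs when it
reaches Nyquist — at 1 kHz sampling that means 450 Hz, and the clamp is
recorded in the envelope's provenance); an IIR biquad notch (50 Hz, Q = 30);
half-wave rectification; envelope smoothing; per-channel normalisation to
the trial maximum (no maximum-voluntary-contraction trial exists in this
protocol, so the trial maximum is the only available reference).

Design notes:

* **Zero-phase filtering.** Processing is offline, so every IIR stage is
  applied forward–backward. The implementation pads with odd reflection
  sized by the slowest pole's settling time (9 time constants): a Q = 30
  notch rings for ~0.2 s, and short fixed padding would leak edge transients
  into the signal. Ringing excited *at* the pad–signal junction by the
  backward pass is unavoidable in principle; it decays within ~0.6 s of the
  trace ends, which is why steady-state filter contracts are asserted on the
  trace interior.
* **Half-wave rectification** (negatives zeroed) is the documented default
  even though full-wave is the more common practice; both are available
  (`rectification = "half" | "full"`). On the simulator's symmetric carrier
  the envelope differs only by a factor ~2 before normalisation, so the
  choice is not load-bearing here.
* **Smoothing** is a 6 Hz 4th-order zero-phase low-pass of the rectified
  signal (the classic linear envelope); a moving-RMS window is offered as an
  alternative. The envelope is clamped at zero afterwards, since a low-pass
  can undershoot slightly on step-like envelopes.
* **Force chain**: notch, bias removal, 2nd-order 15 Hz low-pass,
  normalisation to [0, 1]. The bias (load-cell offset) is the median of the
  true rest segments when ground-truth activation is available (synthetic
  data), otherwise the 1st percentile of the low-passed trace — estimated
  after low-passing so that residual notch ringing at the trace edges cannot
  corrupt the percentile, and low enough that signals without any rest (a
  ramp, say) are not shifted. Rectification of force appears in some
  descriptions of this chain and is provided as an option, off by default.
  Normalisation is on by default; it is what puts RMSE values on the
  "fraction of peak force" scale used throughout.

`frequency_response()` exposes the composed magnitude response of the linear
stages (band-pass × notch, squared for the zero-phase application) so the
filter contract — ≥ 30 dB at 50 Hz, ≥ 20 dB below the low edge, flat
mid-band — is testable against the designed transfer functions rather than
against realisations.

## Features, labels, representations

Windows are 200 ms with a 100 ms hop (long enough for stable amplitude
statistics at these bandwidths, short against the 5 s plateaus). Each window
and channel yields MAV, RMS, VAR, WL, ZC, SSC and IEMG; ZC and SSC use a
deadband of 1% of the channel maximum. Windows are labelled active when the
window-mean cleaned force exceeds 10% of the trial maximum — the force
channel is the only labelling source this protocol offers. The window-mean
force is the regression target.

A second, per-sample representation (`sample_matrix()`) feeds the decimated
envelope values directly as instances (50 Hz default decimation — the 6 Hz
envelope is heavily oversampled at 1 kHz). It exists because pipelines of
this kind are sometimes run sample-wise; the windowed representation is the
package default for both tasks, being ~50× smaller with equivalent accuracy
at these problem sizes.

## Models

**SVM** (`fit_svm()`): soft-margin, Gaussian kernel, defaults C = 1 and
kernel width sigma = 0.5, features standardised inside the solver. Labels
are 0/1 at the interface, −1/+1 internally for the sign-based decision.

**Random forest** (`fit_rf()`): K = 50 trees of depth ≤ 9, Gini splits,
sqrt(d) features per split, bootstrap with replacement. The exact bootstrap
membership counts of every tree are retained, so out-of-bag membership is
reconstructable: `oob_error()` predicts each training sample by majority
vote over only the trees whose bootstrap excluded it and reports the
misclassified fraction among samples with at least one such tree. Samples
in every tree's bootstrap are excluded from the denominator (with 50 trees
this is vanishingly rare). Vote ties break towards the lowest class index,
deterministically.

**SVR** (`fit_svr()`): epsilon-insensitive support vector regression,
Gaussian kernel. Force targets are min-max normalised to [0, 1] before
fitting, so epsilon is a fraction of the force range. Defaults: C = 0.5,
epsilon = 0.03, and kernel width by the median heuristic (half the median
pairwise squared distance of the standardised training features,
`sigma_sq = "auto"`). Two of these deserve their reasoning spelled out:

* *epsilon.* A tube of 0.3 — a value sometimes quoted for this kind of
  model — is geometrically incompatible with sub-0.1 RMSE on [0, 1] targets:
  any function within 0.3 of both the rest level (0) and the plateau level
  (1) has zero epsilon-loss, and the minimum-norm such function sits ~0.3
  from both, capping the achievable fit. With half the signal at each
  extreme, honest force tracking requires the tube to be small against the
  range; 3% leaves the solver insensitive to envelope jitter without
  flattening the estimate.
* *kernel width.* Kernel widths do not transfer across feature spaces: a
  width suited to 3-dimensional envelope samples is far too local for 21
  standardised windowed features, where pairwise squared distances
  concentrate around twice the dimension. The median heuristic is the
  standard data-driven default and any fixed value can be supplied.

The solver is `e1071`/libsvm at tolerance 1e-6 (so near-boundary
support-vector counts are stable in tests); the package's own contract —
dual box constraint, tube KKT conditions, flat degenerate solution, monotone
support-vector count in epsilon — is verified against a brute-force
quadratic-programming oracle on tiny problems.

## The genetic algorithm

One engine (`ga_run()`) drives both uses. Chromosomes are bit vectors;
populations of 20 evolve by roulette selection (tournament offered),
single-point crossover at 0.8, per-bit mutation at 0.01 and one elite copied
unchanged — so the best-so-far fitness is non-decreasing by construction.
Real parameters are encoded as 10-bit *Gray-coded* fixed-point segments over
declared ranges: Gray coding makes adjacent grid points differ in one bit,
removing the Hamming cliffs that stall plain binary encodings near smooth
optima (with plain binary the toy-optimum recovery error was an order of
magnitude larger across seeds). Degenerate ranges (low = high) fix a
parameter and drop it from the chromosome. A failing objective scores as the
generation's worst rather than aborting, unless the entire first generation
fails.

Feature selection maximises `f = W·Acc + (1−W)/Nf` with W = 0.9 by default —
accuracy-dominant, with the 1/Nf term breaking ties towards smaller feature
sets; an empty mask scores 0 so the GA can recover from it. Hyper-parameter
tuning maximises validation accuracy (SVM) or validation R² (SVR) on a
seeded 70/30 split inside the training data — a fixed split rather than
nested cross-validation, which keeps a tuning run at desk scale (a few
hundred model fits); the cost is optimistic fitness values, which is why
tuned models are compared to defaults on the same validation split they were
tuned against, and reported on untouched test data separately. Tuning
ranges: C ∈ [0.01, 10], epsilon ∈ [0.001, 1], sigma² ∈ [0.1, 50] — the upper
sigma² bound is set to cover the median-heuristic width of the default
21-feature representation, so the tuner's search space contains the untuned
default.

## Evaluation

`regression_metrics()` implements MSE, RMSE, MAE and the package's headline
convention: `RSE = sqrt( Σ(ŷ−y)² / Σ|ȳ−y| )`, `R² = (1 − RSE)·100`. Note the
absolute-deviation denominator: this RSE is *not* scale-invariant (scaling
both signals by k scales it by √k), which is a property of the convention,
not a bug; it is well-defined here because metrics are computed on [0, 1]
normalised force. A conventional coefficient of determination is always
reported alongside (`r2_conventional_pct`). Constant observed signals make
the denominator zero and are rejected as degenerate.

`run_protocol()` implements the two protocols: **A** — train on trial 1,
test on trial 2 (both phases reported); **B** — pool the subject's trials,
split 70/30 (seeded; stratified by class for classification), optionally run
10-fold cross-validation inside the training portion for model verification,
then test once on the held-out 30%. Cohort rows are arithmetic means of
per-subject metrics. All splits, folds, forests and GA runs derive their
randomness from the call's seed.

## Problem sizes and numerical choices in the test suite

The suite runs the full study conditions where that is what is being
claimed: the cohort-level acceptance checks use five subjects × two trials ×
30 s at 1 kHz, ten seeds. Component tests use the smallest sizes that
exercise the property (3-point QP oracles, 63-mask exhaustive searches,
27-point tuning grids, 2000-window OOB comparisons), and GA-in-the-loop
tuning runs use 12–15 generations except where the claim is about the
optimiser itself, which runs the full population-20/50-generation setting.
Filter steady-state contracts are asserted away from trace edges (first/last
~0.5–1 s) because zero-phase IIR filtering necessarily rings at the ends of
a finite record.

## Known limitations

* The activation→force map is subject-stationary; no fatigue, potentiation
  or angle dependence. Nothing here addresses joint-angle variation or the
  musculotendon geometry that a biomechanical model would provide.
* The classifiers and regressor are within-subject; no cross-subject
  transfer is attempted or evaluated.
* The electromechanical-delay alignment uses the trial's own force channel;
  online estimation from EMG alone would need a fixed physiological prior
  instead.
* The GA tunes three SVR (or two SVM) parameters against a single inner
  split; with very small training sets the tuned parameters inherit that
  split's noise.
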