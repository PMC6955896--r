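---
title: "Source-space classification of motor imagery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-space classification of motor imagery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sourcebci)
```

## Overview

`sourcebci` implements a source-space analysis of two-class motor-imagery
EEG: right-hand versus right-foot imagery trials are mapped from the
scalp sensors to cortical sources with a standardized minimum-norm
(sLORETA) inverse, collapsed to one time course per somatomotor region of
interest (ROI), classified with common-spatial-pattern (CSP) features and
a linear support vector machine, and finally subjected to exhaustive ROI
subset searches that rank which regions carry the discriminative
information.  A seeded synthetic generator supplies trials with known
ground truth so that every stage of the chain can be validated without
any recording.

This vignette documents the models, their assumptions, the tunable
parameters, and the design choices made where the design was genuinely
open.

## Forward model

The head is a three-shell concentric sphere: scalp, skull and brain
compartments with outer radii 0.090, 0.085 and 0.080 m and
conductivities 1, 0.0125 and 1 S/m (the conventional high
scalp-and-brain / resistive-skull values).  The scalp potential of a
radial unit dipole at radius $b$ is the truncated Legendre series

$$ V(\theta) = \sum_{n=1}^{N} c_n \, P_n(\cos\theta), $$

where the $c_n$ solve, per harmonic order, the continuity conditions of
potential and radial current at the two interior interfaces plus the
no-flux condition at the scalp.  The solver works in radii scaled by the
scalp radius for conditioning and was verified against the closed-form
homogeneous-sphere solution (agreement to machine precision when all
conductivities are equal).

Choices that matter:

* **Truncation** $N = 60$ by default.  Sources sit on a shell at 0.85 of
  the brain radius, where the series tail at $N = 60$ is below $10^{-6}$
  of the column norm (checked against $N = 120$).  Shallower sources
  converge more slowly; the constructor refuses a truncation whose last
  retained term still contributes more than 1% of the largest
  coefficient.
* **Radial, fixed-orientation sources.**  One scalar amplitude per
  location keeps the sLORETA standardization scalar and matches the
  one-time-course-per-location design of the rest of the pipeline.
* **Average reference.**  Lead-field columns are centered across
  electrodes, and every projected sensor sample therefore sums to zero.
* **Electrode montage**: a quasi-uniform golden-angle lattice on the
  upper scalp hemisphere, 32 channels by default; a 118-channel lattice
  is available for fidelity runs.  Neither reproduces a standardized
  10-5 layout; for synthetic work only the geometry matters.

## ROI atlas

Nine somatomotor regions are realized per hemisphere -- S1F, S1H, CMA,
M1F, M1H, SMA, pSMA, PMd, PMv -- as spherical caps of 6 degrees angular
radius, mirrored across the midline.  No public coordinates exist for
these areas on a spherical head, so the default placement encodes the
homuncular ordering instead: foot representations within 15 degrees of
the midline, hand representations 30-45 degrees lateral, somatosensory
areas posterior to the central-sulcus line and premotor areas anterior
to it.  All centers and the cap radius are overridable, and the
constructor rejects configurations whose same-lobe caps overlap.
Sources falling inside two caps (possible near the midline across
lobes) are assigned to the nearer center, deterministically.

## Synthetic trials

Each trial is built in source space and projected through the lead
field ($W = LS$):

* **Background**: every source carries an independent Gaussian process
  with $1/f$ power spectral density (exponent 1 by default), unit RMS,
  synthesized by spectral shaping.
* **Planted effects**: a class-dependent 8-13 Hz band-limited Gaussian
  waveform is added coherently to all sources of a chosen ROI, with RMS
  `amplitude_hand` or `amplitude_foot` by trial label.  The default
  configuration plants a 2:1 hand-over-foot contrast in S1H_L and M1H_L
  and the reverse contrast in S1F_L and M1F_L, emulating lateralized
  mu-rhythm modulation with the hand and foot representations that
  dominate the occurrence tallies of the study design this package
  operationalizes.  The generator treats the effect as a signed
  amplitude contrast only; CSP is indifferent to which class has more
  power.
* **Sensor noise**: white Gaussian noise at `sensor_snr = 1` (noise RMS
  equal to the projected-signal RMS); `Inf` disables it exactly.
* **Splits**: 200 training and 100 test trials by default, balanced
  classes; the test split continues the same seeded stream after the
  training split, so the two are disjoint draws and a run is
  reproducible byte for byte from the seed.

The default operating point (amplitudes 2:1, SNR 1) was chosen once so
that the full pipeline lands in the intended discriminability range --
well above chance on the planted regions but below a ceiling where every
subset would be equivalent.  What the generator does **not** emulate:
ocular/muscular artifacts, line noise, spatially correlated sensor
noise, non-stationary rhythms, inter-subject variability in ROI
placement.  Passing tests on
these data demonstrate internal consistency of the chain, not expected
accuracy on any real recording.

## Preprocessing

Two analysis bands are used: broadband 0.1-30 Hz and the mu rhythm
8-13 Hz.  Filtering is a 4th-order Butterworth band-pass applied forward
and backward (zero phase, squared magnitude response).  Two numerical
choices deserve note:

* Each pass starts from the filter's steady internal state for a
  constant input at the epoch's first sample (the classic `zi`
  initialization).  On 200-sample epochs this matters: the 0.1 Hz band
  edge places poles at $|z| \approx 0.998$, and starting from a zero
  state -- or padding the epoch with reflected samples, whose junction
  kinks carry pass-band energy -- lets those poles ring across the whole
  epoch.  With steady-state initialization a 40 Hz probe retains under
  3% of its RMS through the broadband filter; with reflect padding it
  retained over 30%.
* Epochs are filtered directly (there is no continuous recording in the
  synthetic setting).  Whether the original analysis filtered
  continuously before epoching is unknown; this is flagged as a
  difference, not assumed away.

The epoch window default is the 2 s slice starting 0.5 s after cue
onset when slicing longer trials, skipping cue-onset transients.

## Inverse model

The minimum-norm kernel is $T = L^\top (L L^\top + \alpha H)^{+}$ with
$H$ the average-reference centering operator, identity noise covariance,
and eigendecomposition-based pseudoinversion (relative cutoff
$10^{-12}$) because centering makes $L L^\top$ singular.  sLORETA
standardizes the estimate by the square roots of the resolution-matrix
diagonal, $s_j = \sqrt{(TL)_{jj}}$:

$$ \hat s_j(t) = \frac{(TW)_j(t)}{s_j}. $$

* **Regularization**: $\alpha = \mathrm{tr}(LL^\top)/(n_e\,\mathrm{SNR}^2)$
  with SNR = 3 by default -- the standard minimum-norm convention,
  deterministic and overridable.  The kernel norm decreases monotonically
  in $\alpha$ beyond the largest eigenvalue of $L L^\top$.
* **Zero localization error**: for a single noiseless source the
  standardized power arg-max is exactly the true source; the test suite
  verifies this exhaustively on a 100-source, 32-electrode model.
* Sources invisible to the lead field (all-zero columns) are flagged
  unreachable and the operator refuses to standardize rather than divide
  by zero.

## ROI aggregation

Each ROI is collapsed to a single time course.  Radial orientations on
a curved cap can flip the sign of otherwise coherent sources, so the
default aggregator is a **sign-aligned mean**: members are flipped to
correlate positively with the ROI's first principal direction (sign
fixed deterministically) and then averaged.  An antiphase pair, which a
plain mean would cancel to zero, is recovered at full amplitude.  Plain
mean and first-principal-component aggregation are available as config
alternatives for sensitivity checks.  ROI membership is decided once at
source-space construction (cap containment), not distance-weighted, so
the mapping is deterministic and testable.  One time course per ROI is
the default multiplicity; it bounds the usable CSP filter pairs at
$\lfloor k/2 \rfloor$ for a $k$-region subset.

## CSP and classification

Per-trial covariances are trace-normalized, averaged within class, and
shrunk by $\delta = 10^{-6}$ toward a scaled identity (guarding
three-channel subsets with few trials).  The generalized eigenproblem
$C_\mathrm{hand} w = \lambda (C_\mathrm{hand} + C_\mathrm{foot}) w$ is
solved by whitening the composite covariance; eigenvalues lie in
$[0, 1]$, and the test suite cross-checks the whitening route against an
independent non-symmetric eigensolver.  Features are the log of each
projected variance normalized by the sum over the $2m$ retained filters
(top $m$ and bottom $m$).  Trace normalization is standard CSP practice
but makes the eigenvalues exactly invariant only to orthogonal channel
mixings; with normalization disabled, invariance holds for arbitrary
invertible mixings (both are tested).

The classifier is a linear SVM with margin penalty $C = 1$ on features
standardized with training-split statistics.  The kernel and penalty are
not documented in the study design this mirrors; the linear choice is
the field default for near-linearly-separable CSP log-variance features
and keeps runs deterministic.  An RBF kernel is available behind the
config but excluded from acceptance runs.

Accuracy, sensitivity and specificity are exact rational percentages
with right-hand imagery as the positive class; zero denominators raise
errors rather than returning silent zeros, and rounding happens only at
the reporting layer.

## Subset search

Five exhaustive modes are supported: all $2^9 - 1 = 511$ non-empty
subsets per lobe, all $\binom{9}{3} = 84$ three-region subsets per lobe,
and all $\binom{18}{6} = 18564$ six-region subsets of both lobes.  The
"all subsets" count is read as $2^9$ including the empty set; the empty
subset is unevaluable and skipped, a documented divergence.  Singleton
subsets cannot host a filter pair and are likewise skipped with a
recorded reason.

The front end of the pipeline (filtering, inverse, ROI aggregation) is
computed once per data set; subset evaluations then only slice the
per-trial ROI covariance stacks, which makes the exhaustive searches
desk-scale.  Model selection over subsets and filter-pair counts uses
**test** accuracy, deliberately mirroring the best-result protocol of
the study design; this is an optimistic protocol and is reported as
such, not recommended practice.  Ties for the best accuracy are broken
deterministically (smallest subset, then smallest $m$, then enumeration
order) and all tied subsets are retained; occurrence tallies distribute
one unit per run across ties by default (`1/k` each), with a
winner-takes-all alternative.

## Problem sizes and determinism

Default study conditions: 32 electrodes, 500 sources, 200 training and
100 test trials of 2 s at 100 Hz.  The three-region searches over both
bands, five seeds, run in a few minutes on one core; the full
18564-subset two-lobe search is behind an explicit call at these sizes.
All randomness flows from the single generator seed: the lattice
rotation, labels, background, planted waveforms and sensor noise.
Repeated runs with one seed are byte-identical; the RNG state of the
caller is saved and restored around generation.

## Known limitations

* The spherical geometry, lattice montage and cap atlas are synthetic
  stand-ins, not a template anatomy; absolute accuracies on these data
  say nothing about any specific subject.
* The inverse assumes identity noise covariance and fixed radial
  orientations; colored noise, free orientations and depth weighting
  are out of scope.
* Real recordings in the published competition container (MAT files)
  are not parsed here; no MAT reader is part of the dependency set.
  Trial sets import/export through a plain JSON + CSV archive instead.
* Only the two-class hand/foot problem is implemented; the recorded but
  unused left-hand class of the original protocol is out of scope.
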