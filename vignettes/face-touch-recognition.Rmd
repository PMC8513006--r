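---
title: "Recognizing face touching from wrist-worn accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing face touching from wrist-worn accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristft)
```

## The problem

Spontaneous face touching transfers pathogens from contaminated hands to
the mucosal membranes of the eyes, nose and mouth, which makes it a
transmission vector for respiratory infections. A smartwatch worn on the
dominant wrist carries a tri-axial accelerometer that sees every
hand-to-face movement as a characteristic rotation of the device relative
to gravity. `wristft` implements the full analysis pipeline for turning
such raw 30 Hz acceleration streams into a face-touch recognizer:
preprocessing, windowing, feature engineering, and a participant-grouped
nested cross-validation harness over four standard classifier families.

The package targets a scripted laboratory protocol: ten activities, each
performed repeatedly for 3 minutes, four of which involve the face
("Repeated face touching", "Eating and drinking", "Simulated smoking",
"Adjusting eyeglass" — category FT) and six of which do not (phone use,
lying, computer tasks, writing, leisure walking, moving items — category
NFT). Two recognition tasks are evaluated: binary FT vs NFT recognition,
and 10-class individual activity recognition (IAR).

## The synthetic protocol generator

Real recordings of this protocol exist, but the package is fully testable
without them: `simulate_dataset()` generates the complete study — 10
participants, each performing all 10 activities for 180 s at 30 Hz in a
randomized order with 10 s idle breaks — from a single seed.

Every activity uses the same generative skeleton,

$$\mathbf{a}(t) = \mathbf{g}(\theta(t), \phi) + \mathbf{m}(t) +
  \boldsymbol{\varepsilon}(t),$$

a slowly wobbling unit gravity vector (parameterized by the tilt
$\theta$ of the device x-axis, which runs along the forearm, and a roll
$\phi$), an activity-specific movement component $\mathbf{m}$, and white
Gaussian noise. The movement models are:

* **lying flat** — none; noise floor 0.01 g.
* **phone / computer / writing** — short bursts (15–25 per minute,
  0.5–0.8 s) of low-amplitude jitter (0.04–0.05 g) around nearby static
  postures ($\theta_0$ = 25°, 30°, 35°). These three are deliberately
  similar: distinguishing them is the hard part of IAR, as it is with
  real sedentary activities.
* **leisure walk** — sinusoidal arm swing at 2.0 Hz, 0.3 g, dominantly
  along the forearm axis (the arm hangs nearly vertical, $\theta_0$ =
  80°, so the swing modulates the vector magnitude at the swing frequency
  itself rather than its second harmonic).
* **moving items** — periodic raise–carry–lower cycles at 12 per minute
  (0.2 Hz): the tilt ramps from 15° to 65° over 0.8 s, holds 2.5 s while
  "carrying", and ramps back, with 0.15 g of transient acceleration on
  the transitions.
* **the four FT activities** — randomly timed hand-to-face excursions of
  the same ramp–dwell–ramp form, up to 68–72°, with label-specific rates
  and dwells: repeated face touching 10/min with 1.5 s dwells, eating 5/min
  with 3 s dwells, smoking 4/min with 6 s holds, eyeglass adjustment
  8/min with brief 1 s touches. The rates are set high because protocol
  participants perform each task *repeatedly* for the whole bout; with
  sparser events most windows would contain no face contact at all and
  the window labels would be wrong by construction.

Event rates, amplitudes and noise floors are engineering choices — no
published amplitudes exist for this protocol — fixed once so that two
qualitative facts about the real data hold: leisure walking is trivially
distinguishable from face touching, while moving items (raise–carry–lower)
shadows the FT excursion profile and is genuinely confusable with it.
Between-participant variability enters as log-normal multipliers
($\sigma = 0.15$) on movement amplitude and frequency and a uniform
$\pm 15°$ rotation of the baseline orientation, drawn once per
participant, so leave-one-subject-out folds face a real distribution
shift. All randomness flows through one RNG stream seeded from the
configuration, making every dataset bit-reproducible.

What the simulator does *not* model: transitions between activities
(bouts are cleanly separated by idle gaps), sensor drift and saturation,
gyroscope signals, off-wrist periods, or the irregular timing of
free-living behavior. Passing tests on simulated data therefore
demonstrate that the pipeline is correct and that the protocol's
qualitative structure is recoverable — not that any particular accuracy
will transfer to real recordings.

## Preprocessing

Annotation logs give each activity's start and end. The first 20 s and
last 5 s of every bout are discarded as transition noise, leaving
$3 \times 60 - 25 = 155$ s per bout and $10 \times 10 \times 155 =
15{,}500$ s for the full protocol. Interval membership is half-open,
$[\mathrm{start}+20, \mathrm{end}-5)$, so sample counts are deterministic
and no sample can fall into two segments. Samples between activities are
dropped, not labeled as a rest class. Clocks are assumed synchronized (as
they are in the protocol, where the annotation app is synced to the watch
clock); no drift correction is attempted.

## The 49 features

Each retained segment is cut into consecutive non-overlapping windows of
2–16 s (trailing partial windows dropped) and each window is summarized
by 49 features.

For each of the four signals — vector magnitude
$vm_i = \sqrt{x_i^2+y_i^2+z_i^2}$ and the three axes — eleven summary
statistics: mean, SD, coefficient of variation ($100\,s/|\bar v|$),
minimum, maximum, 25% and 75% quantiles, third and fourth central
moments, skewness and kurtosis (44 features). Two gravity-angle features:
the per-sample tilt $\theta_i = (180/\pi)\arcsin(x_i/vm_i)$ of the
forearm axis relative to vertical, summarized by its mean (`mangle`) and
SD (`sdangle`). Three spectral features of the vector-magnitude series:
the fraction of DFT modulus in the 0.6–2.5 Hz band (`p625`), the dominant
frequency (`df`) and the fraction of modulus at it (`fpdf`).

Numerical conventions, chosen where the feature definitions are silent
and fixed as package constants:

* SD uses the sample ($n-1$) denominator; central moments, skewness and
  kurtosis use population ($n$) moments, the dominant actigraphy
  convention. Kurtosis is plain $m_4/m_2^2$, not excess.
* Quantiles use linear interpolation between order statistics (R's
  default type 7).
* Guards keep every feature finite: $|\bar v| < 10^{-6}$ g sets the
  coefficient of variation to 0; $m_2 < 10^{-12}$ sets skewness and
  kurtosis to 0; $x/vm$ is clamped to $[-1,1]$ before the arcsine.
* The DC term is excluded from all three spectral features — a band
  starting at 0.6 Hz cannot contain 0 Hz, and the DC modulus would
  otherwise dwarf every spectrum, pinning `fpdf` near 1. Ties in the
  dominant frequency resolve to the lowest frequency. No detrending or
  taper is applied before the FFT. A window whose positive-frequency
  moduli are all below $10^{-12}$ (a constant signal) reports
  $(0, 0, 0)$.

Every feature is verified in the test suite against an independent
brute-force implementation (explicit loops, direct-summation DFT) to
$10^{-10}$ relative error, and against closed-form scale laws (scaling
all axes by $c$ scales moments by the right powers of $c$ and leaves the
dimensionless features untouched).

## Nested cross-validation

Hyperparameters must not be tuned on the participant they are evaluated
on. The harness therefore uses nested cross-validation with 10 outer
leave-one-subject-out folds and 3 inner folds: in each outer fold one
participant is the test set, and the 9 remaining participants are
shuffled (deterministically from the plan seed) into three groups of
three. Each grid point is trained on two groups (6 participants) and
validated on the third (3 participants), rotating; the point with the
best mean validation F1 (binary F1 of the FT class, or macro-F1 for IAR)
is refit on all 9 training participants and evaluated once on the test
participant. Ties resolve to the earlier grid row. Features are z-scored
by training-fold statistics in every split — required for the penalized
linear models, harmless for the trees.

Four classifier families are evaluated, each behind an established
implementation: ridge-penalized logistic/multinomial regression
(`glmnet`, grid over inverse regularization $C \in \{0.01, 0.1, 1, 10,
100\}$, mapped to $\lambda = 1/(nC)$), a radial-kernel SVM (`e1071`,
cost $\in \{0.1, 1, 10\}$, kernel scale $\gamma$ at $\{0.5, 1, 2\} /
n_\mathrm{features}$), a pre-pruned decision tree (`rpart`, max depth
$\in \{3, 5, 10, 30\}$, min leaf $\in \{1, 5, 10\}$, complexity penalty
off) and a random forest (`ranger`, $\{100, 500\}$ trees, max depth
$\in \{5, 10, \infty\}$, impurity importance). The glmnet fits descend a
15-point warm-start path to the target $\lambda$ (convergence threshold
$10^{-5}$); the SVM's AUC scores are decision values, not calibrated
probabilities; forests are probability forests only for the binary task,
where ROC scores are needed.

Binary metrics (FT positive): accuracy, recall, precision, F1, and AUC by
the trapezoidal rule over the ROC of score thresholds. Multiclass
metrics: accuracy and unweighted macro recall/precision/F1 over the
classes present in the test fold (a class never predicted contributes
precision 0; a class absent from a fold is excluded from the macro
average with a note — impossible under the full protocol, possible with
user data). Fold metrics are reported as mean (SD) over the 10 outer
folds; a single-class test fold would be excluded from the AUC average
with a warning. The confusion matrix pools the test predictions of all
outer folds before row-normalizing to percentages; forest feature
importances are averaged across the 10 outer-fold forests and scaled so
the maximum is 1.

## Problem sizes and reproducibility

The package's reference experiment — used by the worked example in the
README and by the study-scale tests — is the default simulated protocol
(10 participants, 180 s bouts, 30 Hz, seed 20210930) with 5 s windows:
3,100 windows of 49 features, nested CV as above. At these sizes a single
family's nested CV takes seconds (tree, logistic) to a few minutes (SVM,
forest) on one core. Smaller configurations (fewer participants, 60 s
bouts) are used for the structural unit tests; the window-length sweep
re-runs the full protocol per length and is the most expensive surface.

Every stage is deterministic given its seed: the simulator threads one
RNG stream; the plan shuffles inner groups from its own seed without
touching the global stream; stochastic learners receive seeds derived
from the plan seed and fold index. Two runs of the same configuration
produce byte-identical CSVs and reports.

## Known limitations

* The simulator's between-activity separability is easier than reality:
  real phone use, writing and computer work share postures *and*
  micro-movement statistics, and real face touching is briefer and more
  varied than scripted bouts. Absolute metric levels on simulated data
  should not be read as forecasts for real recordings; the package's
  claims are about pipeline correctness and qualitative structure
  (binary easier than 10-class; moving items confusable with FT;
  walking not).
* An idealized 180 s bout yields exactly 31 five-second windows; real
  recordings run slightly long, so real-data window counts will not
  match the idealized arithmetic.
* The trimming margins (20 s front, 5 s back), window range (2–16 s) and
  the 0.6–2.5 Hz band are protocol constants, not tuned values.
* Only accelerometry is modeled; gyroscope-based features are out of
  scope, as are free-living (unscripted) data, activity transitions and
  on-device inference.
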