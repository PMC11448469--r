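---
title: "Event-based intrapartum risk alerting: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-based intrapartum risk alerting: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgalert)
```

## The problem

During labor, strong uterine contractions intermittently restrict oxygen
delivery to the fetus. When the accumulated hypoxic stress overwhelms fetal
compensation it can produce acidosis and, in the severe case, neonatal
hypoxic-ischemic encephalopathy (HIE). Clinicians monitor cardiotocography —
the fetal heart rate (FHR) and uterine pressure (UP) — and read it as a
sequence of events: baseline segments (BAS), accelerations (ACC),
decelerations (DEC) on the FHR, and contractions (CON) separated by resting
intervals (RIN) on the UP. Visual assessment of these events is notoriously
variable between observers, which motivates an automated risk score built
directly on event annotations.

`ctgalert` implements a complete pipeline from event-interval annotations to
intervention recommendations, together with a synthetic labor-event
generator, so that every stage of the pipeline can be exercised, calibrated,
and validated without access to clinical recordings.

## Data model

All times are expressed in **seconds before delivery** (delivery = 0), since
every downstream analysis is anchored at the delivery instant. An event
interval runs from a larger `start` down to a smaller `end` and is half-open
at the delivery side, so adjacent events can share a boundary without
overlapping. Records carry a group label (`healthy`, `acidosis`, `HIE`), an
observed Caesarean indicator, a duration of at most 12 h, and a list of
uninterpretable segments — spans where noise prevented event annotation. FHR
events need not tile the record: unlabeled gaps are legal and are distinct
from uninterpretable segments.

## Epoch features

Records are cut into 20-minute epochs counted backwards from delivery
(epoch `k` ends `k * 20` minutes before delivery). An epoch is usable when at
least 80% of its span is interpretable; the remaining epochs are kept as
explicit placeholders because the decision rule needs to know which grid
slots are missing. The interpretability fraction is measured in continuous
time.

Each valid epoch yields 11 features of the event process viewed as a
semi-Markov chain:

* six ordered FHR transition counts (BAS→ACC, ACC→BAS, BAS→DEC, DEC→BAS,
  ACC→DEC, DEC→ACC), and
* five total dwell times in seconds (BAS, ACC, DEC, CON, RIN), i.e. the
  summed intersection of each label's intervals with the epoch window.

Two conventions required a decision that the source problem statement leaves
open:

* **Transition adjacency.** Annotated event streams contain gaps, so
  "consecutive" needs a tolerance: two chronologically adjacent FHR events
  of different labels count as a transition when the gap between them is at
  most `gap_tolerance` (default 60 s, configurable). Transitions across
  longer uninterpretable stretches are not counted, and same-label
  successions never count (the embedded chain must change state).
* **Boundary epochs.** A transition is assigned to the epoch containing the
  later event's start instant; instants on a grid boundary belong to the
  closer-to-delivery epoch, matching the half-open interval convention.

## The balanced epoch classifier

A random forest (default 2,500 trees; 300 in the package's own test and
reproduction runs, see *Problem sizes*) discriminates healthy from
pathological (acidosis or HIE) epochs. Pathological epochs are a small
minority, so every tree is grown on a **balanced bootstrap**: `m` draws with
replacement from each class, `m` being the minority count. The forest is fit
by `ranger` with per-class sampling fractions; per-tree in-bag sets are
retained and the epoch probability is defined as the fraction of trees
voting pathological — for training epochs, the fraction among the trees that
excluded the epoch from their bag (out-of-bag, OOB). Epochs that appear in
every bag have no OOB value and propagate to the decision stage as missing
rather than being imputed. Tree depth is unlimited and `mtry = 3` (the
standard square-root default for 11 features); these are exposed in
`forest_config()` but not tuned by the package.

The bootstrap is taken at epoch level while the train/test split is strictly
at subject level. Within a training set, epochs of one subject may therefore
appear across trees; across the evaluation boundary no subject ever
contributes to both sides.

## The consecutive-alert decision rule

An epoch raises an alert when its probability strictly exceeds a threshold
`pt`. Intervention is recommended the first time the last `n` consecutive
grid epochs all alert, tolerating up to `floor(n/2)` missing epochs in the
window; with more missing epochs the system defers. Until `n` epochs have
elapsed the "last n epochs" do not exist and the system is likewise
deferred, so the earliest possible recommendation is after `n` × 20 min of
monitoring (100 min at the selected run length 5). We read the missing-epoch
budget "n/2" as `floor(n/2)` — the conservative choice for odd `n` — and
require at least one observed epoch in the window: a window of only missing
slots never recommends. A recommendation latches: once issued it persists,
making subject-level detection curves cumulative. Deferral does not reset a
run; the window test is simply re-applied at the next epoch.

`(n, pt)` are calibrated on training data only:

* For each `n` in 1–10, a subject-level ROC curve is swept over all distinct
  OOB probabilities (plus 0 and 1) as thresholds; `n̂` maximizes the
  trapezoidal AUC, ties broken toward smaller `n` (earlier decisions).
* `p̂t` is the smallest threshold whose training false positive rate (the
  healthy-group recommendation rate) stays at or below the target — by
  default the healthy group's observed Caesarean rate, so the system
  recommends no more healthy interventions than obstetric practice already
  performs.

The threshold sweep uses an exact reduction: a subject is recommended at
threshold `pt` if and only if the maximum over admissible windows of the
window's minimum observed probability exceeds `pt`. This collapses the ROC
construction to a ranking problem and is asserted against direct rule
evaluation in the test suite.

Whether the original system built its ROC at epoch or at subject level is
ambiguous; this package uses the subject level, because the quantity being
optimized is the discrimination of the recommendation system after
aggregation, and `roc_for_n()` operates on per-subject probability streams.

## Evaluation

`evaluate_cohort()` repeats the full pipeline over independent stratified
90/10 subject splits (100 by default; each iteration's seed derived from a
root seed). Summaries are medians with distribution-free order-statistic
95% confidence intervals (binomial ranks at n ≥ 8). Group recommendation
rates at chosen epochs — by default those ending 3 h and 40 min before
delivery — are compared to the group's observed Caesarean rate with a
two-sided one-sample Wilcoxon signed-rank test across iterations; the
comparison test is this package's choice, made because the per-iteration
rates are paired with a fixed comparator and need no normality assumption.
The Caesarean comparator is computed on the full cohort, not per split.
Median probability trajectories pool epochs across subjects within a group.
A subject still deferred at the end of its record counts as not recommended.

## The synthetic cohort generator

No generative model of labor events is available to us, so the simulator is
the package's own construction, designed to emulate the statistical
structure the classifier exploits rather than waveform physiology:

* Each channel is a semi-Markov chain: an embedded transition matrix with
  zero diagonal and log-normal dwell times per state (positive support and
  heavy right tails typical of event durations). The UP chain is a forced
  alternation of CON and RIN.
* Pathology expresses as decelerations: the BAS→DEC entry probability and
  the DEC dwell mean rise linearly as delivery approaches. The drift weight
  is `w(t) = floor + (1 - floor) * max(0, 1 - t/horizon)` with a 6 h
  horizon. Healthy labor has a mild ramp (entry +0.10, dwell ×1.25 at
  delivery, floor 0) — labor is stressful for every fetus, and risk scores
  are expected to rise toward delivery in all groups. The acidosis and HIE
  groups add a constant elevation (floor 0.25) and stronger ramps (entry
  +0.30/+0.45, dwell ×2/×3), making HIE the most severe. These values were
  fixed once, as a plausible severity ordering with clear separation near
  delivery and mild separation far from it; they are configuration, not
  fitted estimates.
* Generation runs chronologically from record start toward delivery; the
  drift weight of an interval uses its start instant, keeping the dynamics
  causal.
* Uninterpretable segments arrive as a Poisson process (default 1/h,
  exponential durations with mean 90 s). FHR events overlapping them are
  split at the segment boundaries; fragments shorter than 5 s are dropped.
* Cohort composition defaults to the 37,546 : 3,056 : 374
  healthy/acidosis/HIE proportions with per-group Caesarean probabilities
  0.389 / 0.376 / 0.549; group counts use largest-remainder rounding, and
  record durations are uniform on 4–12 h (capped at 12 h). Each record has
  its own seed substream derived from the root seed, so cohorts are
  reproducible.

What the generator does **not** emulate: any coupling between contractions
and decelerations (the channels are independent given the group's drift
clock — a documented extension point), clinical covariates, gestational age,
drug effects, or detector-specific annotation biases. Passing tests on
synthetic cohorts therefore demonstrate the correctness and calibration
behavior of the pipeline, not clinical performance: headline detection
rates on real cohorts cannot be reproduced from simulation.

## Numerical choices and degenerate inputs

* Validation reports violations instead of throwing, and is total on
  arbitrary interval lists.
* Transition-matrix rows must sum to 1 within 1e-9; dwell conservation
  across the epoch grid holds to 1e-6 s.
* A run length `select_n()` tie is broken toward smaller `n`; a threshold
  constraint that no grid value satisfies yields `pt = 1` with a warning
  (nothing can alert at `pt = 1` under the strict inequality).
* `median_ci()` requires at least 8 values, the smallest sample for which
  the 95% order-statistic interval is comfortably defined; the Wilcoxon
  comparison requires the same and returns `p = 1` when all differences are
  zero.
* Records shorter than one epoch featurize to zero rows; a duration shorter
  than the first sampled dwell yields a single truncated event per channel.

## Problem sizes

The package's own validation runs use desk-scale versions of the study
conditions, chosen to exercise every code path with stable statistics: a
2,000-subject cohort (default composition), 300-tree forests, and 10
evaluation iterations for calibration and separation checks; a
1,200-subject cohort with identical group dynamics for null behavior; and
10,000-draw Monte-Carlo checks for generator recovery. `scripts/acceptance.R`
re-runs the 2,000-subject, 10-iteration pipeline from scratch and writes the
resulting policy, AUC, calibration, and per-group recommendation rates to
JSON.

## Known limitations

* The simulator's independence of the FHR and UP channels understates the
  contraction-deceleration coupling of real labor; UP dwell features are
  consequently less informative in synthetic cohorts than they may be in
  practice.
* Out-of-bag probabilities are noisier than full-forest probabilities; the
  calibrated threshold transfers this small bias to the test set, which the
  calibration tests bound (median healthy test rate within 0.05 of target).
* Epoch-level bootstrap accepts within-training-set subject correlation
  across trees; OOB discrimination estimates are therefore slightly
  optimistic relative to a subject-level bootstrap. The subject-level
  train/test split keeps the reported test curves unbiased.
* With very small groups (e.g., a handful of HIE subjects in a test split),
  per-group rates are coarse; medians across iterations remain meaningful
  but single-iteration HIE curves should not be over-read.
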