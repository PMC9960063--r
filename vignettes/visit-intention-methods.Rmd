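---
title: "Predicting visit intention from gaze data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting visit intention from gaze data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeintent)
```

## The problem

A user browsing a dynamic one-page website distributes visual attention over
*areas of interest* (AOIs): semantically coherent groups of page components
such as a navigation bar, news groups, advertising banners, and a
registration pop-up. Given an eye tracker's gaze log (120 Hz samples,
fixations, and interaction events such as scrolling and pop-up opening), the
task is to predict, for each future time window of length $\tau$ seconds,
which AOIs the user will fixate. The prediction target for window $v(t)$ is
the binary *visit-intention* vector
$IV(v(t)) = [I_v(A_1, v(t)), \dots, I_v(A_n, v(t))] \in \{0,1\}^n$, where
$I_v(A_j, v(t)) = 1$ exactly when some fixation overlapping the window
hit-tests to AOI $j$. This is a multilabel classification problem whose
instances are time windows.

Two ideas drive the method. First, because little data is available per
user, a *population-level* feature (`Heat_AOI`) injects the window-wise AOI
visit frequencies of the training users into each individual's model.
Second, *visual kinematics* of the previous window — gaze position,
velocity and acceleration — capture where the eyes are heading as a window
opens.

## Signal model and preprocessing

A recording is a sequence of gaze samples $x_i = [x_i, y_i, T_i]$ plus
fixations (quasi-stationary episodes of roughly 100–300 ms), saccades
(ballistic transitions of 30–80 ms characterized by amplitude), and
interaction events. Fixations shorter than 100 ms are filtered out; the
comparison is strict, so a fixation of exactly 100 ms survives. When no
external fixation log is available, the package's dispersion-threshold
(I-DT) detector finds maximal sample windows whose summed x+y dispersion
stays within a bound (default 60 px) for at least the minimum duration.
Invalid samples (blinks, track loss) are excluded everywhere, and temporal
gaps longer than 2.5 nominal sample intervals break difference chains so
that derivatives are never taken across signal dropouts.

Gaze is recorded in screen coordinates. Page-fixed components are
hit-tested after adding the scroll offset, a right-continuous step function
of the scroll events; sticky components (the menu bar) are tested directly
in screen space, before the page layer. Rectangle containment is half-open
($x_0 \le x < x_1$), which makes shared borders deterministic. While the
pop-up is open, only its rectangle can be hit and every other AOI is
deactivated: a fixation on occluded territory counts as whitespace. AOI
attribution is decided at fixation *onset*, since the pop-up state can
change mid-fixation.

## Windows and window-balanced folds

A recording of length $T$ yields $\lfloor T/\tau \rfloor$ windows; the
partial remainder is discarded. A fixation overlapping a window boundary
labels both windows (any temporal overlap counts — the label measures
whether attention touched the AOI during the window).

Cross-validation partitions *users*, never windows, so train and test never
share a user. Because browsing times differ, users are assigned to the $K$
folds (default 10) by minimizing $\sum_k |x_k - \bar{x}|$, where $x_k$ is
the window total of fold $k$ — the absolute deviations being the standard
linearization $U_k \ge x_k - \bar{x}$, $U_k \ge -(x_k - \bar{x})$ of the
underlying integer program. The package solves this exactly with a compiled
branch-and-bound (decreasing-size ordering, symmetric-branch elimination,
and the admissible bound $2\sum_k \max(0, x_k - \bar{x})$, which is valid
because fold excesses can only grow). An exhaustive-enumeration oracle
cross-checks the optimum on small instances in the test suite. Note that
the plain objective $\sum_k (x_k - \bar{x})$ would be degenerate — it is
constant at zero — which is precisely why the absolute-deviation form with
the $U_k$ variables is the one implemented.

## Features

Each prediction instance is a window $t \ge 2$ of one recording (window 1
is dropped rather than zero-filled: every family needs window $t-1$, and
zero-filling would fabricate a "nothing happened" history). Three families
are computed; all unobserved quantities fall back to 0.

**Visit history.** Per AOI: time since last visit (`tslv`, seconds; 0 both
for "never visited" and "visited exactly at the window start" — an overload
kept for compatibility with the feature's definition), activation flags of
the previous three windows (`r1`–`r3`, 0 when the lag precedes the
recording), and a one-hot of the AOI in which window $t-1$ ended, summarized
by $End\_r1 = \sum_j j \cdot AOI\_end\_r1_j$. Per component: an ever-visited
flag, `tslv`, the mean fixation duration on the component (`atv`, ms), the
mean gap between consecutive fixations on it (`atbv`, ms), a one-hot of the
last component fixated in window $t-1$, and the shared integer `Comp_end`
index of that component. The population feature
$Heat\_AOI_j(t) = \sum_u AOI_j(v_u(t)) / U_{train}$ is the fraction of
*training-fold* recordings whose label at the same window index is active;
it is recomputed per fold and test users never contribute.

**Kinematics** (18 features). Over the valid samples of window $t-1$: last
position, mean and sd of position, and central-difference velocity (px/s)
and acceleration (px/s²) series per axis — last value, mean, and sd of
each. Derivatives are estimated only at interior points of each unbroken
sample chain (edge samples serve as neighbors only): one-sided edge
estimates are biased one order lower, which would contaminate the
"last value" features, whereas interior central differences are exact for
linear velocity and quadratic acceleration profiles — properties the test
suite asserts analytically.

**Oculomotor history** (8 features). Counts and mean/max/min summaries of
all fixation durations and saccade amplitudes over the entire interaction
before the window starts (the full span, not a truncated horizon). Only
saccades *completed* before the window count — a saccade still in flight at
the window boundary would leak future information.

Causality is a package invariant, enforced by a test that ablates all of a
user's data from the window start onward, and all other test-fold users
entirely, and verifies every feature of the instance is bit-identical.

## Balancing, selection, and classifiers

**MLSMOTE.** Label imbalance is structural: the pop-up AOI is active in a
small fraction of windows. On training folds only, each label whose
imbalance ratio `IRLbl` (majority count over label count) exceeds the mean
`MeanIR` becomes a seed set: every instance carrying it spawns one
synthetic instance interpolated toward a random one of its 5 nearest
minority neighbors, with labels set by majority vote over seed + neighbors.
Binary feature columns are rounded back to $\{0,1\}$ after interpolation,
which is otherwise ill-defined for flags. `IRLbl`/`MeanIR` are evaluated
once on the input rather than re-evaluated per label pass; with one pass
per minority label the two conventions coincide on the sizes used here.
Test sets are never balanced.

**Feature selection.** Features are ranked greedily against the labels
using discretized mutual information in bits: `MLMIM` by multilabel
relevance (sum of per-label MI), `MLMRMR` by relevance minus mean MI with
already-selected features, `MLJMI` by mean joint MI of the candidate paired
with each selected feature, and `FSCORE` by summed per-label Fisher scores.
Ties break by column index. Floor discretization is the reference scheme;
the pipeline uses equal-width binning (10 bins) because flooring
pixel-scale columns yields alphabets of hundreds of symbols and therefore
badly biased MI estimates at fold sizes of ~10³ instances. `MIFS` and
`RFS` are accepted as strategy names but raise a clear not-implemented
error; their algorithms are defined in external work the package does not
reproduce. The multilabel aggregation for `MLJMI`/`MLMRMR` is sum (mean)
over labels — a documented choice where toolbox conventions differ.

**Classifiers.** Binary relevance (BR) fits one base model per label;
classifier chains (CC) augment the input with the true earlier-chain labels
at training time and with hard predictions at prediction time (default
chain order: AOI 1..6). Bases: ridge regression with an unpenalized
intercept and closed-form solution (grid $\lambda = 0.25{:}0.25{:}2$), kNN
scoring the positive-neighbor fraction (grid $K = 5{:}5{:}30$, Euclidean
distance, distance ties broken by training index), and a linear-kernel SVM
delegated to `e1071` (grid $C = 0.2{:}0.2{:}2$) whose decision values are
used for ranking. ML-kNN ($k = 15$, Laplace smoothing $s = 1$) computes
smoothed label priors and neighbor-count likelihoods and scores the
posterior. Features are standardized with training-fold statistics — the
distance-based bases require it. Hard predictions threshold the score at
0.5 (0 for SVM decision values) with the $\ge$ convention. The *reference
configuration* — `best_model_config()` — is KNN-BR with $K = 20$ and 10
MLMIM-ranked features at $\tau = 5$ s, the configuration that maximizes
accuracy and subset accuracy.

## Metrics

With $Y_i$ the true and $Z_i$ the predicted label sets of instance $i$:

* **macro AUC**: per label, the fraction of (positive, negative) pairs with
  $r(x', y_l) \ge r(x'', y_l)$ — ties count as successes, so an all-tied
  label scores exactly 1 — averaged over labels that have both classes;
  degenerate labels are excluded with a warning rather than imputed.
* **accuracy**: mean Jaccard index $|Y_i \cap Z_i| / |Y_i \cup Z_i|$;
* **subset accuracy**: exact-match rate $[\![Y_i = Z_i]\!]$;
* **precision** $|Y_i \cap Z_i|/|Z_i|$ and **recall**
  $|Y_i \cap Z_i|/|Y_i|$, per-instance terms averaged;
* **F-measure**: $2PR/(P+R)$ on the aggregated precision and recall.

Zero-denominator conventions (the formulas are silent): empty union
contributes 1 to accuracy, an empty prediction contributes 0 to precision,
and an empty true set contributes 1 to recall (vacuously recovered). The
majority-class (MC) baseline reports, per AOI, the modal label value and
its frequency (ties at 0.5 report class 1), and for the whole vector the
modal vector's frequency; a constant MC predictor's per-AOI accuracy equals
the MC ratio, which the tests assert as a cross-module consistency check.

## The synthetic cohort generator

Real gaze corpora of this kind are rarely redistributable, so the package
ships a first-class generator used by the tests and the acceptance script.
Each user is a semi-Markov process over 7 states (6 AOIs + whitespace):
every state visit is one fixation at a uniform point inside a member
component, with log-normal dwell (median 220 ms) truncated to the observed
fixation range [100, 3273] ms, separated by 30–80 ms saccade gaps, sampled
at 120 Hz. Transition rows mix a self-transition probability (~0.72, giving
runs of a few fixations and hence label variation at $\tau = 5$ s) with
preference vectors that drift over the recording — early browsing favours
the top of the page, late browsing the bottom. This shared drift is the
planted population structure that makes `Heat_AOI` informative for held-out
users. Per-user preferences are log-normal perturbations (scale 0.4) of the
population vector. Scroll events keep page-fixed targets visible below the
sticky bar; entering the pop-up state opens the occluding pop-up and leaving
it closes it, so with zero noise every generated fixation re-attributes to
its generating AOI through the hit-tester — an exactness the tests require
at 100%. Whitespace is an explicit state so all-zero label vectors occur
and exercise MLSMOTE; the pop-up preference (~3%) keeps AOI 6 rare, which
reproduces the heavy label imbalance this kind of data shows. Recording
lengths default to a truncated log-normal with mean ≈ 79 s and sd ≈ 52 s
within [16.5, 399] s; the default cohort is 51 users × 3 recordings.

What the generator does *not* emulate: saliency-driven guidance by page
content, reading-order micro-structure within components, smooth pursuit,
and calibration drift. Passing tests therefore demonstrate that the
pipeline recovers planted population and kinematic structure — not that
real websites are predictable at any particular level.

## Experiment orchestration and problem sizes

`run_experiment()` wires the stages per fold: fold assignment → labels →
features (Heat from training users only) → MLSMOTE on the training fold →
feature selection on the (balanced) training fold → fit → score the test
fold. Everything downstream of the raw data is deterministic given the
seed, and re-running reproduces the report exactly (timing columns aside).
Classification time is measured around the scoring call only and reported
per window, the quantity that decides online feasibility (it must stay
below $\tau$). `sensitivity_analysis()` repeats the experiment over
$\tau \in \{3, 5, 10, 15, 20\}$ s.

The test suite and acceptance script use cohorts of 10–20 users × 2–3
sessions × 60–90 s with $K \in \{3, 5, 10\}$ — sizes chosen so the full
suite completes in a few minutes while every instance count stays large
enough (≈10³ windows) for stable metric estimates. Model selection, where
several configurations are compared, uses test-fold means, maximizing
accuracy and subset accuracy with precision reported prominently; an inner
validation split would be preferable for unbiased configuration choice and
is an acknowledged limitation of the protocol the package reproduces.

## Worked example

```{r example, eval = FALSE}
pop <- sample_population(n_users = 10, sessions = 2, duration_s = 60, seed = 1)
recs <- simulate_cohort(pop, seed = 1)
report <- run_experiment(recs, pop$layout, tau_s = 5, K = 5, seed = 1)
report
report$mc$per_aoi
```

## Known limitations

* The fold-assignment branch-and-bound is exact but worst-case exponential;
  a node cap (default 5·10⁷) returns the best incumbent with a warning on
  adversarial instances far beyond the study scale.
* `tslv = 0` is ambiguous between "never visited" and "just visited", as
  defined.
* CC feeds *hard* chained predictions forward; probabilistic chaining is
  not implemented.
* The SVM base reports ranking AUC from decision values, which are not
  calibrated probabilities.
* Non-rectangular AOIs, grid segmentation, pupil-based features and
  velocity-threshold (I-VT) fixation detection are out of scope.
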