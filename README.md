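# gazeintent

Predicting **visit intention** — which areas of interest (AOIs) of a dynamic
one-page website a user will fixate in the next time window — from
eye-tracker gaze data.

Browsing a modern web page changes its layout continuously: the page
scrolls, a menu bar sticks to the viewport, a registration pop-up occludes
the content underneath. `gazeintent` predicts a user's attention on such a
layout *without* tracking its structure at every instant. Each recording is
segmented into τ-second windows; the target of window `v(t)` is the binary
vector `IV(v(t)) = [Iv(A_1, v(t)), …, Iv(A_n, v(t))]` over the `n` AOIs,
where `Iv(A_j, v(t)) = 1` iff the user fixates AOI `j` during the window.
Multilabel classifiers (binary relevance and classifier chains over ridge /
kNN / linear-SVM bases, plus ML-kNN) predict this vector from three feature
families:

* **visit history** per AOI and per page component (time since last visit,
  recent-window activations, where the previous window ended), including
  the population-level `Heat_AOI_j(t) = Σ_u AOI_j(v_u(t)) / U_train`, the
  training users' visit frequency at the same window index;
* **visual kinematics** of the previous window (gaze position, velocity,
  acceleration in X and Y, by central differences);
* **oculomotor statistics** over the whole interaction so far (fixation
  counts/durations, saccade counts/amplitudes).

Around the classifiers, the package implements the full experimental
pipeline: I-DT fixation detection and the strict < 100 ms fixation filter,
AOI hit-testing with scroll, sticky components and pop-up occlusion,
window-balanced user→fold assignment by an exact optimizer
(min Σ_k |x_k − x̄| over fold window totals), MLSMOTE oversampling of
minority labels on training folds, mutual-information multilabel feature
selection (MLMIM / MLJMI / MLMRMR / F-score), ranking and example-based
evaluation metrics (macro AUC, subset accuracy, accuracy, precision,
recall, F-measure, per-AOI accuracy, majority-class baselines), and a
semi-Markov synthetic browsing-cohort generator for end-to-end testing.

## Worked example

```r
library(gazeintent)

pop  <- sample_population(n_users = 20, sessions = 3, duration_s = 90, seed = 1)
recs <- simulate_cohort(pop, seed = 1)
rep  <- run_experiment(recs, pop$layout, list(best_model_config()),
                       tau_s = 5, K = 10, seed = 1)
rep
#> <eval_report> tau = 5 s, 10 folds
#>  config   auc subset_accuracy f_measure accuracy precision
#>  KNN-BR 0.742           0.161     0.732    0.574     0.702
rep$mc$vector_mc$ratio
#> [1] 0.1027778
```

The reference configuration (`best_model_config()`: kNN binary relevance,
K = 20 neighbors, 10 MLMIM-ranked features, τ = 5 s) reaches macro AUC
0.742 and subset accuracy 0.161 on this seeded synthetic cohort — well
above the trivial majority-class predictor, whose whole-vector ratio is
0.103. `sensitivity_analysis()` repeats the experiment over
τ ∈ {3, 5, 10, 15, 20} s and reports per-window classification time (which
must stay below τ for online use).

A thin command-line front end lives at `inst/cli/gazeintent.R`
(`simulate`, `run-all`, `sensitivity` subcommands).

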