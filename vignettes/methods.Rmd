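---
title: "Methods: explainable AutoML for iliac-vein stent occlusion risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explainable AutoML for iliac-vein stent occlusion risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stentrisk)
```

## The prediction problem

One-year occlusion of an implanted iliac-vein stent is a binary outcome
with a low event rate (around 15%) driven by several interacting factor
families: the etiology spectrum (post-thrombotic syndrome, deep-vein
thrombosis, Cockett/May–Thurner compression and their combinations, with
the DVT + Cockett + PE triad the highest-risk class), 30-day
recanalization rates of the external iliac, common femoral and femoral
veins, inflammation and coagulation biomarkers (CRP, D-dimer, APTT, PT,
fibrinogen), stent geometry (diameter, total length, extension into the
inferior vena cava) and the postoperative anticoagulation regimen.
`stentrisk` models this outcome from a 22-predictor tabular record with a
gradient-boosted-tree classifier whose feature subset and hyperparameters
are chosen by a metaheuristic, and wraps the model in a discrimination /
calibration / net-benefit evaluation layer and a LASSO + Shapley
interpretability layer.

## The ISequoiaOA optimizer

Both AutoML stages are driven by a population metaheuristic modelled on
sequoia-forest dynamics. The published account of the algorithm names its
two improvements — chaotic initialisation and dynamically scaled
Lévy-flight steps — but not the base update equations, so the concrete
operator set here is this package's own design, isolated behind the
`iseq_optimize()` interface so it can be swapped:

1. **Canopy growth.** Every agent moves towards the incumbent best with a
   coefficient annealed linearly from 2 to 0; because the random factor
   can exceed 1 early on, agents overshoot the best and explore around it,
   which is what makes the best itself improve.
2. **Seed dispersal.** A random half of the agents receive a Lévy
   perturbation `α(t)·L·range` with Mantegna steps (`β = 1.5`,
   `σ_u = 0.6966`) and scale `α(t) = α₀·e^{−4t/T}` (`α₀` = 0.1 of the box
   range). Heavy tails give occasional long jumps out of local basins;
   the exponential decay hands the end of the run over to exploitation,
   reaching about 1.8% of the initial scale at the final iteration. The
   step is scaled by the box range rather than by the distance to the
   incumbent best: distance scaling collapses once the population
   converges, which would cancel exactly the late-run refinement the
   decay schedule exists to provide (and, measured on the benchmark
   suite, makes the "improved" variant lose to the constant-scale
   baseline on unimodal functions).
3. **Fire renewal.** The worst 10% of agents are re-initialised
   chaotically each generation, which keeps a trickle of global
   exploration alive at any stage.

Initialisation is a *chaotic Latin hypercube*: one logistic-map orbit
(`x ← 4x(1−x)`, the fully chaotic regime; degenerate orbit points 0, ¼,
½, ¾, 1 rejected) per dimension supplies within-stratum jitter after
uniformisation through the arcsine CDF of the map's invariant density,
and a seeded permutation assigns strata. Plain chaotic scaling alone
concentrates points near the box faces (the arcsine density is
U-shaped) and actually *worsens* minimum pairwise distances; the
stratified construction is what delivers the wider spread the chaotic
initialisation is meant to buy, and the package tests assert that
property directly. The plain `SequoiaOA` baseline differs from
ISequoiaOA exactly in the two published improvements: uniform
initialisation and a fixed (non-decaying) Lévy scale.

Boundary handling is clipping, chosen over reflection for determinism
and simplicity. Non-finite objective values discard the candidate with a
warning and the run continues. The benchmark harness substitutes the
official CEC2022 function data files (external, licence-bound) with 12
standard functions — sphere, ellipsoid, Rosenbrock, Rastrigin, Ackley,
Griewank, Zakharov, Levy, Schwefel 2.22, Alpine, sum-of-powers, expanded
Schaffer — whose optima are shifted to a seeded random point inside the
box so no algorithm profits from an origin bias. The study protocol is
dimension 10, population 30, 500 iterations, 30 runs; the package's own
checks run the same protocol at 100 iterations and 10 runs so the whole
suite stays within desk-scale compute, a size at which the
ISequoiaOA-vs-SequoiaOA median ordering is already stable.

## Dual-stage AutoML

**Stage 1 (feature mask).** Positions in `[−4, 4]^22` decode to masks
through the sigmoid transfer `P(bit_j = 1) = 1/(1 + e^{−x_j})`; an
all-zero draw is rescued by switching on the bit with the largest
transfer probability. **Stage 2 (hyperparameters)** then searches the
unit box mapped onto: trees 50–500, depth 2–8, learning rate 0.01–0.3,
row subsample 0.5–1, minimum child weight 1–20, L2 penalty 0–10
(integers rounded at evaluation). The stages are sequential — stage 2
conditions on the stage-1 mask — with no alternation. The default point
(150 trees, depth 4, η 0.1) is always evaluated in stage 2, so tuning
can never end below it.

The shared fitness is the mean out-of-fold ROC-AUC over stratified
5-fold cross-validation minus a parsimony penalty of `0.01 ×`
(fraction of bits set), which makes an 11-of-22 mask preferable to the
full mask whenever it costs less than 0.005 AUC. Inside every fold,
standardisation parameters are fitted on the fold-training rows only and
SMOTE (k = 5 nearest minority neighbours, synthetic points
`x_i + u·(x_nn − x_i)` with `u ~ U(0,1)`, minority grown to near parity)
is applied to the fold-training rows only; the validation fold is never
touched. The learner is an xgboost gradient-boosted tree ensemble,
single-threaded and seeded, chosen for tabular performance and exact
tree-Shapley compatibility; it sits behind a two-function interface
(`fit`/`predict`) so another learner could be substituted.

A deliberate oddity is `paper_mode` in `compare_models()`: the
published cross-validation and test metric tables are arithmetically
consistent only with evaluation partitions that were themselves
SMOTE-rebalanced (test-set prevalence ≈ 0.42 against a printed split
prevalence of 15.15%). That protocol inflates apparent performance and
is scientifically questionable, so the package reproduces it only under
the explicit flag and never by default.

## Evaluation layer

Threshold metrics use `p ≥ t → positive` with `t = 0.5` by default
(configurable). ROC-AUC is computed as the Mann–Whitney probability with
ties counted ½ (identical to the trapezoid); PR-AUC uses the
average-precision step rule, avoiding the optimism of linear PR
interpolation. Calibration uses 10 equal-width bins plus the Brier
score; decision curves evaluate net benefit
`NB = TP/N − (FP/N)·p_t/(1−p_t)` on the 0.01–0.99 grid with treat-all
and treat-none references (treat-all crosses zero exactly at the
prevalence). The threshold tie rule, the grid and the bin count are this
package's choices; the sources are silent on all three.

## Interpretability layer

The LASSO validation step fits an L1-penalised logistic path on the
standardized design (one-hot categoricals, first level as reference)
through glmnet's warm-started coordinate descent at a tight convergence
threshold (1e-11), over a 100-point grid spanning four decades below the
smallest all-zero lambda; glmnet's deviance-progress rule may truncate
the grid where the fit saturates, which matters for small cohorts whose
near-MLE tail is quasi-separable. Selection uses `lambda_1se` on
cross-validated deviance — deviance, not misclassification, because the
event rate is low. Correctness is asserted by an independent
Karush–Kuhn–Tucker subgradient oracle (`lasso_kkt_violation`): every
returned solution must satisfy `|X_j'(y − p)|/n ≤ λ` for inactive
coefficients and equality with sign for active ones, to 1e-6.

Shapley attributions use the exact path-dependent tree algorithm for the
boosted-tree learner (log-odds scale; local accuracy
`base + Σφ = margin` holds to numerical tolerance) and a
permutation-sampling estimator with antithetic pairs for arbitrary
models. The sampling estimator walks every background row for every
permutation, so each permutation telescopes and local accuracy holds
*exactly*; for additive models the estimate is exact regardless of the
number of permutations. Per-feature Monte-Carlo standard errors come
from the spread across permutation pairs. Global importance ranks mean
|φ| with one-hot columns aggregated back to their source variable by
summing per-sample contributions (ties break alphabetically).
Threshold-interaction summaries split samples into the four quadrants of
a feature pair (e.g. CRP > 10 mg/L × D-dimer > 1.5 mg/L), average the
pair's joint contribution per quadrant and report the synergy excess
`m_HH − m_HL − m_LH + m_LL`, flagged when it exceeds twice its pooled
standard error; for a purely additive model with independent features
this excess is zero in expectation.

## Synthetic cohort generator

No patient-level data are available, so the generator emulates the study
population and makes every downstream claim testable as a recovery
property. Marginals are read off the published training-column table:
normal variables by mean/SD (age 58.92 ± 12.43 y, surgery time
86.51 ± 24.36 min, stent length 98.73 ± 25.52 mm, diameter
14.29 ± 2.17 mm, PT, APTT, EIV recanalization truncated to [0, 100]%);
right-skewed variables by a three-parameter (shifted) log-normal solved
by root-finding to reproduce the printed median *and* both quartiles
exactly (hospital stay, fibrinogen, D-dimer 1.25 [0.78–1.96] mg/L, CRP
8.6 [4.2–14.3] mg/L); variables whose printed quartiles are symmetric
(BMI, IVC extension, CFV/FV recanalization) admit no such log-normal and
fall back to a (truncated) normal with `sd = IQR/1.349`; categorical and
binary variables by their printed frequencies (etiology 32.5/26.9/15.4/
18.3/6.8%, anticoagulation 47.2/45.1/7.7%); stent count by a small pmf
with median 1 and upper quartile 2. Predictors are sampled
independently — the sources report no correlation structure — and a
correlation hook is deliberately left out of scope.

The outcome model is logistic. Its terms encode the reported effect
structure: ordinal etiology weights peaking at the triad (0, 0.25, 0.35,
0.8, 1.6); protective linear slopes for CFV and EIV recanalization;
positive slopes for D-dimer and CRP; protective thresholds for stent
diameter > 14 mm and IVC extension > 20 mm (the sources themselves
disagree on the direction of the length effect; the Results-section
direction is used); a no-anticoagulation main effect with an additional
APTT slope active only in that group; a CRP > 10 × D-dimer > 1.5
synergy (+0.55); and a both-recanalizations-below-70% interaction whose
coefficient is *solved by root-finding* so that switching it on exactly
doubles the occlusion probability at the cohort-typical covariate point.
The intercept is calibrated by bisection so the Monte-Carlo mean event
probability (100 000 fixed-seed draws) hits the 15.5% target within
0.002; because the doubling coefficient and the intercept depend on each
other, the two solves alternate to a joint fixed point. Remaining effect
magnitudes are design choices sized so that the three intended strongest
effects (etiology, CFV recanalization, D-dimer) dominate; all
coefficients live in the spec object (JSON-serialisable), none are
hard-coded in the sampling path.

What passing recovery tests on these data does *not* show: robustness to
correlated predictors, to covariate shift between centres, to
informative missingness (records are always complete here), or to
real-world effect sizes — the planted effects are only as realistic as
the qualitative claims they were solved from.

## Problem sizes, numerics, determinism

The package's own test suite and the acceptance script run everything at
desk scale on one CPU: benchmark protocol 12 × 2 × 10 runs × 100
iterations; AutoML recovery at the study cohort size (n = 826) with
3-fold CV, stage budgets 12 × 10 and 8 × 6, and trees capped at 150 —
sizes at which the planted-signal recovery is already stable while a
full fit stays around twenty seconds. Interaction-recovery checks use
n = 2500 per seed: only about 14% of samples land in the
doubly-elevated CRP/D-dimer quadrant, and the 2-standard-error synergy
flag needs several hundred of them for adequate power. Every stochastic component takes
an explicit seed (child streams derived by a fixed affine map kept below
2^31), RNG state is saved and restored around seeded internals, and
identical seeds reproduce identical masks, hyperparameters, benchmark
tables and pipeline artifacts byte for byte. Degenerate inputs have
defined behaviour throughout: zero pooled variance with equal means
gives t = 0 (unequal means is an error), empty masks are rejected,
all-negative mask positions rescue one bit, SMOTE refuses minorities
smaller than k, and an undefined precision (no predicted positives) is
reported as 0 with a warning.

## Known limitations

The SequoiaOA operator set is a reconstruction — fidelity to the
original authors' exact update equations is unverifiable from the
published description. Comparator models run at library defaults
(the published setup states none), so the zoo comparison measures the
AutoML pipeline against *untuned* baselines, mirroring the original
asymmetry. The published headline test metrics (ROC-AUC 0.9251, Brier
0.123) are properties of an unavailable real cohort and are not
reproduction targets; the synthetic analogues live in the acceptance
report instead. Nested cross-validation for unbiased generalisation
estimates is out of scope by design.
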