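---
title: "Methods: enhanced learners, ensembles and risk subgroups for imbalanced CHD cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhanced learners, ensembles and risk subgroups for imbalanced CHD cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chdrisk)
```

`chdrisk` implements a complete modelling protocol for binary coronary
heart disease (CHD) risk prediction on survey-style cohorts where the
outcome is rare. This vignette documents the statistical machinery, the
parameters that matter, the synthetic data the package is validated on,
and the design choices taken where more than one reasonable construction
exists.

## The data model

A `cohort` is a numeric feature matrix, a strictly binary outcome, and
per-feature metadata: a *kind* (`binary`, `ordinal`, `continuous`) and a
*domain* (`demographic`, `clinical`, `behavioral`, `healthcare`). The kind
drives how a feature is imputed, standardised and interpolated; the domain
drives the subgroup analysis. Preprocessing (`preprocess()`) runs KNN
imputation, IQR and Mahalanobis outlier *flagging*, variance filtering and
standardisation, in that order. Outliers are reported, never silently
deleted: whether a flagged survey row is an error or a legitimate extreme
is a judgement the analyst must make, so removal is an explicit option
(`drop_outliers`).

Numerical conventions worth stating once:

* quantiles use the linear-interpolation (type-7) rule, so the IQR toy
  examples are exactly reproducible;
* a singular covariance in the Mahalanobis step is ridge-regularised by
  `1e-6 · trace(Σ)/d` on the diagonal rather than failing;
* missing cells are `NA`; mode imputation for binary/ordinal features
  breaks ties toward the smaller category value;
* z-scoring skips binary features so their 0/1 coding survives.

## Class imbalance

`smote_balance()` implements the canonical synthetic minority
oversampling rule `x_new = x_i + λ(x_nn − x_i)` with `λ ~ U[0,1]` per
synthetic row, neighbours found by Euclidean distance on z-scored
features, drawn uniformly among the `k = 5` nearest minority neighbours.
The synthetic count is chosen by integer arithmetic so the
minority:majority ratio hits `target_ratio` exactly (default 1, i.e.
50/50). Binary features are thresholded at 0.5 after interpolation: the
interpolation rule is defined in a continuous feature space and says
nothing about categorical outputs, and thresholding is the smallest
modification that keeps binary features binary. Consequently the exact
on-segment geometry holds for continuous features; for binary features
the synthetic value is one of the two parent values.

Balancing belongs on the training partition only. Oversampling before the
train/test split would place synthetic near-copies of test-adjacent
minority points into training data and inflate every test metric; the
functions therefore leave the ordering to the caller, the benchmark
harness balances after splitting, and the CLI exposes the
balance-then-subsample ordering as an explicit choice.

`yamane_sample_size()` computes `n = N / (1 + N e²)` rounded to the
nearest integer. At the canonical inputs `N = 459,574`, `e = 0.01` the
formula evaluates to `459,574 / 46.9574 = 9787.04`, i.e. 9,787 — a figure
sometimes quoted as ≈9,789; the implementation returns the formula's own
arithmetic and the discrepancy is documented rather than matched.

## The four enhanced learners

**ANRDT (soft-split tree).** The tree structure is learned by ordinary
greedy Gini splitting; each internal node is then assigned a sigmoid gate
`f(x) = 1/(1 + e^{β(x−θ)})` giving the probability of routing *left*
(the `x ≤ θ` branch), so `β → ∞` recovers hard CART routing exactly —
this orientation is a package convention, chosen so the hard-tree limit
is an exact oracle. The steepness is `β = β₀/s_j` with `s_j` the split
feature's training standard deviation, so gates blur over a fixed
fraction of each feature's natural spread; `β₀ = 4` by default (roughly:
the gate moves from 0.12 to 0.88 across one standard deviation). The
softening is post-hoc — structure from hard splits, finite `β` afterwards
— because nothing forces `θ` and `β` to be learned jointly, and the
post-hoc construction keeps the equivalence oracle exact. Pruning
generates the weakest-link cost-complexity sequence of the hard tree and
picks the subtree whose *softened* predictions minimise validation
log-loss.

**HIRF (hybrid imbalanced random forest).** Each of `n_trees = 200`
(defaults; tests and the benchmark use fewer) trees is grown on a
SMOTE-balanced bootstrap with `√d` feature subsampling per split, so
every tree sees a balanced class mix. Trees are combined as
`ŷ = Σ wᵢ Tᵢ(x)`. The tree weight is a contribution score: the mean, over
validation rows, of the probability the tree assigns to the row's true
class minus 0.5, clipped at zero, normalised to sum to one
(`hirf_tree_weights()`). This is the tree-level instantiation of
"credit each tree for pushing predictions toward the truth": uninformative
trees score 0 and are excluded, identical trees share weight equally, and
the weights are permutation-equivariant. A single-class validation set
falls back to uniform weights with a warning.

**PGBM (pruned gradient boosting machine).** Stagewise boosting on the
margin scale: labels are encoded ±1, the model state `F` is half the
log-odds (`p = plogis(2F)`), and each round fits a depth-3 regression
tree to the negative gradient of the Huber loss of the margin residual
`y± − F`. Applying the Huber loss to margin residuals rather than class
probabilities keeps its quadratic-near/linear-far structure meaningful
for classification: a confidently mislabeled point contributes a bounded
gradient `±δ` (default `δ = 1`) instead of an unbounded one. Early
stopping monitors validation log-loss with `patience = 10` rounds and
retains the best round seen, so the retained model's validation loss is
by construction no worse than the final round's. The `loss = "logistic"`
configuration of the same engine (gradient `y − p`, `F` on the log-odds
scale, first-round prediction equal to the prior) is the plain GBM
baseline.

**ESVM.** The RBF-kernel dual is solved by SMO-style pairwise coordinate
ascent with first-order working-set selection: at each step the
maximal-violating pair is updated analytically under
`0 ≤ αᵢ ≤ C`, `Σαᵢyᵢ = 0`, and ascent stops when the largest
Karush–Kuhn–Tucker violation falls below `1e-3`. Hyperparameters are
searched on `(log₁₀C, log₁₀γ) ∈ [−2,3]×[−4,1]` by a small Gaussian
process (RBF kernel, length-scale 0.3 on unit-box coordinates) maximising
expected improvement of 5-fold CV accuracy over a fixed evaluation
budget. Because the hinge-loss machine has no native probabilities, a
one-dimensional logistic (Platt-style) calibration is fitted to the
decision scores on validation data. The solver holds the full kernel
matrix, so training size is capped (2,000 rows by default); inputs are
expected standardised and a warning fires when non-binary feature SDs
leave `[0.5, 2]`.

The baseline configurations (`fit_cart()`, `fit_rf_baseline()`,
`fit_gradient_boost(loss = "logistic")`, `fit_svm_baseline()`) are thin
reference settings of the same internals — hard splits, uniform tree
weights, squared/logistic loss, fixed `(C, γ)` — so enhanced-vs-baseline
comparisons isolate the enhancement rather than implementation
differences.

## Ensemble combiners

All five combiners operate on any learners exposing `predict_prob()`.

* **AdaBoost**: depth-1 stumps (the conventional weak learner; depth is a
  parameter), weighted error `ε_m`, learner weight
  `α_m = ½ln((1−ε_m)/ε_m)`, multiplicative weight update renormalised each
  round. `ε_m = 0` is floored at `1e-10` before the log; `ε_m ≥ 0.5`
  triggers one re-draw with random feature subsampling, then stops.
* **Bagging**: bootstrap resamples, majority vote, vote share as the
  probability.
* **Stacking**: the meta-feature matrix `Z` holds base-learner
  *probabilities* (not hard labels — the logistic meta-learner
  presupposes continuous inputs) on the hold-out validation rows, so test
  rows never enter meta-feature construction; the meta-learner is IRLS
  logistic regression, falling back to a ridge-stabilised IRLS
  (`λ = 0.01`) under separation.
* **Voting / averaging**: modal class with ties broken by mean
  probability against 0.5, a residual exact tie resolving to the positive
  class (the clinically conservative direction); probability averaging is
  the plain mean.
* **BMA**: the marginal likelihood of a fitted black-box learner is not
  computable, so the model evidence is approximated by the exponentiated
  validation log-likelihood with uniform model priors, normalised through
  log-sum-exp; candidate probabilities are floored at `1e-12` so one
  overconfident zero cannot produce an infinite deviance. This keeps the
  posterior-ratio structure of Bayes' theorem with a tractable surrogate
  for the evidence.

The default "enhanced ensemble" base set is {ANRDT, HIRF, PGBM, ESVM} and
the "baseline ensemble" set is {CART, RF, GBM, SVM}; which learners enter
an ensemble is a convention of this package, exposed as an argument.

## Evaluation

Predicted positive means score ≥ 0.5 unless a threshold is given — stated
explicitly because every confusion matrix depends on it. Metrics with a
zero denominator return `NA` with a warning rather than 0, so
fold-averaged summaries are not silently deflated. AUC uses the
tie-corrected midrank (Mann–Whitney) form, which equals the trapezoidal
area when tied scores cross thresholds simultaneously — the relevant case
for tree ensembles with few distinct probabilities. Average precision is
the step-interpolated threshold sweep. Calibration curves use 10
equal-width bins, omitting empty ones. Cross-validated reports average
metrics over stratified folds.

## Risk subgroup analysis

For each domain (and the full feature set): z-score encoding of
non-binary features, k-means (Lloyd iterations from k-means++ seeding,
best of 10 restarts by the objective `J`, empty clusters reseeded at the
farthest point), `k` chosen by mean silhouette over 2..10 with ties to
the smaller `k`, a Pearson chi-square test of the cluster-by-outcome
table (no continuity correction, df = k−1), and a logistic regression of
the outcome on cluster dummies with the lowest-labelled cluster as
reference. The table reports `OR = e^β` and Wald intervals
`e^{β ± 1.96·SE}`; complete separation switches to a ridge-stabilised
IRLS fit flagged in the output. All predictors in this package's feature
template are binary or ordered, so z-scoring suffices; one-hot encoding
would be needed only for unordered categoricals. Whether clustering
should see SMOTE-balanced or original data is genuinely undecidable in
the abstract; the package clusters original (pre-balancing) data by
default because subgroup prevalence estimates are only interpretable on
real class frequencies.

## Explainability

`shap_exact()` enumerates all `2^M` coalitions (capped at M = 12) with
absent features marginalised over a background sample — the
interventional value function — and satisfies local accuracy
`f(x) = φ₀ + Σφᵢ` to machine precision. `shap_sample()` is the standard
permutation estimator, unbiased with Monte-Carlo error shrinking as
`1/√n_perm`. Attribution is on the probability scale, matching the "pushes
the predicted risk up or down" reading clinicians expect; the background
is a seeded sample of training rows (100 by default). The surrogate
explainer fits a depth-limited hard CART to the model's predicted labels
on half the data and reports fidelity — plain label agreement — on the
other half. HIRF's tree weighting deliberately reuses the same
contribution idea at tree level rather than feature level; feature-level
attributions of a HIRF model remain available through the generic
Shapley functions.

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* of a large U.S. telephone
health survey: 21 predictors with realistic names, types and marginal
rates (e.g. a 13-band age scale, a 1–5 general-health score, a continuous
BMI around 28), spread over the four domains, and a binary outcome drawn
from a logistic model on z-scored features plus Gaussian noise. The
intercept is solved by bisection on the realised latent scores so the
expected prevalence hits the target (default 9.42%, the imbalance regime
the methods are designed for) exactly in expectation. Effect sizes
default to a plausible risk-factor profile (age, blood pressure,
general health and mobility dominating; physical activity protective);
they are inputs, not claims. `generate_clustered()` plants mixture
structure by shifting domain features along fixed random directions
scaled in SD units and, optionally, tilting the outcome odds per cluster
— enabling recovery experiments for both the clustering and the
odds-ratio pipeline.

What the generator does *not* emulate: real survey marginals and their
dependence structure, measurement error, missing-data mechanisms beyond
MCAR, and the scale of the original data. Passing tests therefore
demonstrate that the algorithms are implemented correctly and behave as
designed under controlled conditions — not that any particular accuracy
level transfers to real BRFSS-like data.

## Problem sizes and determinism

The test suite and benchmark run at deliberately modest sizes — cohorts
of a few hundred to 20,000 rows, forests of 5–50 trees, boosting to ~60
rounds, SVM tuning budgets of 4–6 evaluations — chosen so the full suite
executes in well under a minute while still exercising every code path
at the scale where its properties (oracle equivalences, calibration
bands, recovery rates) are checkable. Every stochastic function takes an
explicit seed, restores the caller's RNG state, and re-runs
bit-identically; model persistence uses 17-significant-digit JSON so
reloaded models predict identically.

## Known limitations

* The SMO solver is dense `O(n²)` in memory; very large cohorts need
  subsampling (the Yamane utility exists for exactly this).
* Exact Shapley enumeration is limited to 12 features; beyond that the
  sampling estimator is the only route.
* Split and fold assignment are seeded by row position: two cohorts that
  are row permutations of each other produce splits identical in size
  and class composition (and the package tests this), but not the same
  row-level assignment — content-addressed randomisation was judged not
  worth the complexity.
* The stacking meta-learner sees single hold-out predictions (the
  protocol implemented here); an out-of-fold variant would use training
  data more efficiently at the cost of refitting every base learner per
  fold.
* Ordinal features are treated as numeric throughout; explicitly ordinal
  models (proportional odds, isotonic splits) are out of scope.
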