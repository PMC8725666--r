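---
title: "Cost-sensitive learning strategies for high-dimensional imbalanced data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-sensitive learning strategies for high-dimensional imbalanced data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costlearn)
```

## The problem

Gene-expression classification tasks routinely pair two pathologies: a few
dozen to a few hundred biological samples are described by thousands of
continuous features (instances-to-features ratios of 0.004-0.14), and the
class of clinical interest -- the *positive* class, by the minority-positive
convention -- makes up only 8-25% of the samples. A learner trained to
minimize overall error on such data can achieve high accuracy while never
predicting the minority class at all. `costlearn` implements, as a tested
library plus a small CLI, a family of *hybrid* strategies that attack both
pathologies at once: ranking-based feature selection against the
dimensionality, and cost-sensitive meta-learning against the imbalance.

## The cost model

A 2x2 cost matrix `C(i, j)` gives the price of classifying a true-class-`i`
instance as class `j`. Correct predictions cost 0, a false positive costs
`C(-,+)` (fixed at 1 by convention) and a false negative costs `C(+,-) = c`,
the one tunable cost. Two classifier-agnostic mechanisms derive from it:

* **Minimum-expected-cost thresholding.** Given a probability estimate
  `P(+|x)`, the expected cost of predicting negative is `P(+|x) * C(+,-)`
  and of predicting positive is `(1 - P(+|x)) * C(-,+)`. Choosing the
  cheaper label is equivalent to predicting positive whenever
  `P(+|x) >= pth` with `pth = C(-,+) / (C(-,+) + C(+,-))`; the package
  tests verify this equivalence on a 101-point probability grid for every
  cost setting used. Ties at exactly `pth` classify positive (the rule is
  `>=`), so the two formulations never disagree, including at the boundary.
* **Instance reweighting.** Each instance receives the misclassification
  cost of its class as a raw weight; `weights_from_costs()` then rescales so
  the total weight equals the instance count I. The rescaling keeps the
  effective sample size, and therefore the base learner's hyper-parameter
  behaviour, comparable across cost settings; it also makes the weights
  invariant to jointly rescaling both costs. Whether a reference
  implementation preserves total mass in this way is an implementation
  detail that published descriptions rarely pin down, so exact numeric
  agreement with other toolchains is not guaranteed -- the package treats
  mass preservation as its own documented convention.

## The six ranking heuristics

All rankers return a permutation of the features with non-increasing
scores, accept per-instance weights, and break score ties by the lower
original feature index (a stable rule chosen purely for reproducibility;
scores themselves are invariant to instance order).

* **CORR** -- absolute weighted Pearson correlation between the feature and
  the 0/1 class indicator. Constant features score 0.
* **IG / GR** -- information gain `H(Y) - H(Y|X)` and gain ratio
  `IG / SplitInfo`, in bits (`0 log 0 := 0`). Continuous features are first
  discretized by recursive binary splitting with the MDL acceptance rule
  (Fayyad-Irani style), the customary supervised discretization for
  expression data. All counts -- including the total used in the
  `log2(N-1)/N` acceptance term -- are sums of instance weights, so integer
  weights behave exactly like replicated instances. A feature with no
  accepted cut collapses to one bin and scores 0; `SplitInfo = 0` (single
  bin) gives `GR = 0` by convention. Candidate cuts are midpoints between
  consecutive distinct values; gain ties go to the lowest cut value.
* **ReliefF** -- every instance serves once as the probe (m = I, the
  deterministic variant), with `k_neighbors = 10` hits and misses by
  default (the customary neighbourhood size; clamped to what a class can
  supply). Distances are Manhattan on range-normalized features and the
  per-feature `diff` is `|a - b| / (max - min)`, so constant features score
  0 exactly.
* **SVM-AW** -- absolute components of the weight vector of a linear
  maximum-margin classifier fitted on internally standardized features
  (weighted zero mean / unit variance; `|w|` is scale-sensitive, and
  standardizing is the behaviour users of attribute-evaluation tooling
  expect). The fit solves the L2-regularized squared-hinge primal
  (`reg = 1` by default) in the span of the training rows, which makes the
  cost of a fit quadratic in the instance count rather than linear in the
  feature count -- decisive at 2,000-12,000 features -- and the smooth loss
  lets a quasi-Newton solver converge deterministically. Non-convergence
  raises an error carrying the solver code rather than returning a silent
  partial ranking.
* **SVM-RFE** -- recursive elimination: refit, drop the
  `ceiling(p/100 * remaining)` lowest-|w| features (at least one, so
  termination is guaranteed), repeat; `p = 50%` by default, a compromise
  between ranking quality and the number of refits. At `p = 100%` the
  method degenerates to SVM-AW, which the tests assert. Because |w| values
  from different rounds are not comparable, reported scores encode
  `(rounds survived) + |w| / (1 + max |w| of the round)` -- monotone in the
  elimination order and non-increasing along the ranking.

### Weighted ReliefF: weights as multiplicities

The package had a genuinely open design choice in how ReliefF should consume
instance weights. The simplest definition -- scale each probe's contribution
by its weight and leave the neighbour search untouched -- fails a property
the rest of the weighted-ranking machinery satisfies: that integer weights
behave exactly like physically replicated instances. Replicating an instance
changes the neighbourhood structure (the probe acquires zero-distance copies
of itself as nearest hits), which contribution-scaling alone can never
reproduce. `costlearn` therefore interprets weights as multiplicities
throughout: a probe contributes in proportion to its weight, a probe of
weight w > 1 contributes mass w - 1 of itself at distance zero to its own
hit pool, and neighbour mass is accumulated along the distance ordering up
to k, with the boundary neighbour entering fractionally. With unit weights
this is the classic k-NN ReliefF; with integer weights it equals the
replicated-data computation with the same k, and the test suite asserts
both. The one consequence worth knowing: weights are on the scale of
instance counts, so only the weight vector's values -- not merely its
direction -- matter (the cost-derived weights, which sum to I, sit naturally
on that scale).

## The base learner and the five strategies

The classifier is a 100-tree random forest, each split choosing the best of
`floor(log2(n)) + 1` random candidate features, where n is the
post-selection feature count (selection always precedes induction, so the
candidate count tracks the reduced dimensionality). Trees are grown to
purity and `P(+|x)` is the across-tree average of leaf class proportions --
smoother than raw vote fractions, which matters because threshold-moving at
small `pth` is sensitive to probability granularity. The forest itself is
delegated to `ranger` (the contract the package pins down in tests is tree
count, per-split candidate count, instance-weight support, probability
semantics, and seeded determinism -- not the tree-growing code). Cost
sensitivity enters by weighting, not resampling.

`run_strategy()` evaluates one of six strategies per cross-validation
partition, always ranking on the training split only (a poisoning test
asserts test folds cannot influence selection):

| strategy | selection | induction | prediction |
|---|---|---|---|
| `BASELINE` | none | uniform | `p >= 0.5` |
| `FS_MI` | uniform weights | uniform | `p >= 0.5` |
| `WFS_MI` | cost weights | uniform | `p >= 0.5` |
| `FS_WMI` | uniform | cost weights | `p >= 0.5` |
| `FS_MCMI` | uniform | uniform | `p >= pth` |
| `ALLFEAT_MCMI` | none | uniform | `p >= pth` |

At `c = 1` the three FS variants coincide exactly, which the tests assert.
Rankings are recomputed inside every training fold rather than once per
dataset: the evaluation protocol repeats the *overall* learning process on
each of the 20 partitions, and per-fold selection is the reading that avoids
selection bias. This choice can produce small differences from analyses
that rank once on the full data.

Seed discipline: a cross-validation plan owns one seed; the forest of
partition t uses `plan_seed + 7919 * t`. Identical inputs and seeds give
byte-identical result tables.

## Evaluation protocol

Performance is summarized by MCC, G-mean and F-measure (plus sensitivity,
specificity, precision), averaged over a 5-fold stratified cross-validation
repeated 4 times -- 20 partitions, each 80%/20%. Stratification deals each
class's shuffled indices round-robin into folds. Degenerate-table
conventions: MCC is 0 when any marginal is zero, rates are 0 on empty
denominators, F is 0 when sensitivity + precision is 0.

Paired strategy comparisons use the Wilcoxon signed-rank test across the 20
partitions, Holm-Bonferroni corrected with k = the number of candidate
strategies. Zero differences are discarded (with n reduced) and tied
absolute differences get mid-ranks -- the classic treatment; partition-level
metrics tie often, so the policy is load-bearing and is therefore
implemented in-package with an exact tie-aware null (generating-function
convolution) up to 25 informative pairs and a continuity- and tie-corrected
normal approximation beyond. Published analyses seldom state whether their
Wilcoxon was exact, so small p-value differences against other software are
expected; against `stats::wilcox.test` the package agrees exactly wherever
both produce exact p-values.

## The synthetic benchmark generator

`generate_dataset()` draws a class-conditional Gaussian: d informative
features shifted by `effect_size` (in within-class-sd units) in the positive
class, optionally equicorrelated within the informative block, plus D - d
independent noise features; class counts are exact, and the RNG stream is
consumed in a fixed order (informative block, then noise) so changing one
setting does not silently shift unrelated draws. Defaults in the tests and
the acceptance script mirror the benchmark regime the package targets:
D = 2000 features, d = 20 informative, 10 positives vs 190 negatives (5%
minority), effect size 1. These sizes keep the full test suite near a
minute while staying inside the instances-to-features and imbalance ranges
of real expression benchmarks.

What the generator does *not* emulate: heavy-tailed intensities, batch
effects, gene-gene correlation beyond one equicorrelated block, and
label noise. Passing tests on this generator therefore demonstrate the
machinery's correctness and the qualitative ordering of strategies on
clean Gaussian data, not the exact performance numbers any particular
real dataset would give.

## What the synthetic experiment shows

In the default regime the cost-blind forest -- with or without selection --
almost never predicts the minority class, so its G-mean is near zero, while
`FS_MCMI` at `c = 5` attains a clearly positive G-mean on every generator
seed (the acceptance checks assert a mean improvement above 0.1, a margin
fixed from an initial Monte-Carlo calibration). This reproduces the
qualitative headline -- hybrid selection + cost-sensitivity dominates
selection alone, which is at least as good as the baseline -- in a regime
harsh enough that selection alone cannot lift G-mean off zero. The cost
parameter should grow with the imbalance; in these experiments values
beyond 5 mostly buy false positives.

```r
d <- generate_dataset(synth_config(10, 190, 2000, 20, effect_size = 1, seed = 101))
plan <- make_cv_plan(d, seed = 201)
base <- run_strategy(d, strategy_spec("BASELINE"), plan)
hyb  <- run_strategy(d, strategy_spec("FS_MCMI", "corr", 0.02, fn_cost = 5), plan)
compare_strategies(list(hyb), base, metrics = "g_mean")
```

## Known limitations

* Binary classification only; multi-class ReliefF and multi-class costs are
  out of scope.
* Dense, complete matrices only: missing values are rejected rather than
  imputed, and the sparse ARFF dialect is not read.
* ReliefF's k, the SVM regularization constant and the internal
  standardization are defaults a user may need to revisit when chasing
  exact agreement with other toolchains on real benchmarks.
* The forest is the only base learner; swapping it for another
  probability-producing classifier is future work the meta-learning layer
  was designed not to preclude.
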