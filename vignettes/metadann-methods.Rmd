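---
title: "Methods: decision-tree routed neural meta-prediction of miRNA targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-tree routed neural meta-prediction of miRNA targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metadann)
```

## Overview

`metadann` classifies miRNA:mRNA pairs as interacting or not using only
the numeric outputs of four established target predictors: miRanda,
miRDB, PITA and TargetScan. The design answers two practical problems
with such score compendia. First, the four tools score on incompatible
axes, so scores are min–max scaled onto a common (−1, 1) interval.
Second, for most pairs only some tools produce a score at all, so the
model is not one classifier but eleven — one per *availability pattern*
(all four tools; each combination of three; each pair), with every
record routed to exactly the module trained on its pattern. Patterns
with a single score carry too little information to integrate and are
not classified.

Each module stacks a dual-threshold, two-step significance-voting
decision tree with a small feedforward neural network that consumes the
tree's intermediate quantities alongside the scaled scores.

## Score scaling

Each predictor spec carries its native range and default cutoff:
miRanda (−1.364, −0.1) with cutoff −1.0; miRDB (50, 100) with cutoff
80; PITA (−43.24, 21.4) with cutoff −10; TargetScan (−9.05, 0) with
cutoff −0.36. miRDB scores high-is-better and is negated before the
affine map, so every scaled axis has predicted interactions toward −1.
The default cutoffs land at −0.424, −0.2, 0.028 and 0.920:

```{r}
round(scaled_default_cutoffs(), 3)
```

Raw values outside the published ranges occur in real dumps and are
clamped to [−1, 1] after mapping rather than rejected; the affine map is
exactly invertible (`unscale_score()`) for in-range values.

## The voting tree

Per predictor the tree holds four cutoffs ordered
`t_true_1 ≤ t_true_2 < t_false_2 ≤ t_false_1`. A predictor votes "true"
at level L when its score is strictly below `t_true_L`, "false" when
strictly above `t_false_L`, and abstains in between. Strict inequality
matches the "<" convention of the published default cutoffs. The
decision sequence is: strict-majority vote under the stringent level-1
cutoffs; on a tie, under the relaxed level-2 cutoffs; on a second tie,
significance voting — the side with the larger aggregate excursion of
scores beyond its level-2 cutoffs wins, with the excursions aggregated
as a Euclidean norm (a plain-sum alternative is selectable via
`aggregate = "sum"`; both are implemented because the two descriptions
of the statistic differ, and the Euclidean reading is the default).
Abstaining predictors contribute zero excursion.

An exact significance tie — including the fully abstaining case
0 == 0 — resolves to "false". Negatives outnumber positives roughly
10:1 in interaction data, so the uninformative case defaults to the
majority class; the tie side is configurable.

The network's feature vector is the module's n scaled scores followed
by the six tree quantities `N_T1, N_F1, N_T2, N_F2, d_T2, d_F2` —
10, 9 or 8 inputs for 4-, 3- or 2-predictor modules. The per-predictor
signed distances from the level-1 and level-2 cutoffs are exposed for
diagnostics (`threshold_distances()`) but deliberately not fed to the
network, which would break those widths.

## Threshold selection by information gain

Candidate cutoffs come from the information-gain curve
IG(x) = H(parent) − Σ_j f_j(x) H(group j), in bits, with groups
"score > x" and "score ≤ x" (the formula is symmetric in the group
orientation). The curve is evaluated on an even grid over the observed
range (default 1000 points; tests and tuning use coarser grids) plus,
for sets under 5000 records, every observed-score midpoint, so each
achievable split is represented. Local maxima are merged across
plateaus (one representative per run, the smallest score), ranked by IG
with ties broken toward the smaller score, and the top four spikes per
predictor (plus one grid step to either side) form the candidate pool.

Tuning is coordinate-wise in four fixed phases — level-1 true, level-2
true, level-1 false, level-2 false — sweeping predictors in the
canonical order miranda, mirdb, pita, targetscan. Within a phase the
active cutoff steps through its candidates in order of proximity to the
current value; a move is kept when the evaluator's accuracy does not
decrease, and after two consecutive strictly lower evaluations the
parameter is frozen. A move that violates the cutoff ordering triggers
repair of the dependent level-2 cutoff to the nearest admissible
candidate; irreparable moves are skipped, so every returned set
satisfies the ordering invariants and never scores below the initial
set. The evaluator is the tree's own training-set accuracy: thresholds
are fixed before any network training, keeping the tree variant ("C-I")
self-contained and the tuning cheap. Overall tree accuracy is used as
the objective; per-move accuracies are retained in the tuning history
for inspection, since a per-branch objective is also defensible.

The tuned four-predictor cutoffs shipped as a fixture
(`d4_thresholds()`) are, per predictor, level-1 true/false
(−0.179/0.844, −0.702/0.059, −0.449/0.257, 0.896/0.982) and level-2
true/false (0.067/0.199, −0.480/−0.269, −0.203/−0.107, 0.964/0.972).

## The network

A fully connected net with hidden layers of 10 and 20 nodes and a
2-node output layer. Every node, output included, applies the
hyperbolic tangent; the two output activations are then exponentially
normalized, O_i^T = exp(O_i)/Σ exp(O_i). Applying the normalization to
*post*-tanh activations bounds the logits to (−1, 1) and therefore the
probabilities to about (0.12, 0.88); that is a faithful rendering of
the stacked activation-then-normalization design rather than the
conventional softmax-on-linear-output, and the 0.5 decision rule is
unaffected. Positive samples are encoded [1, 0], negatives [0, 1].

Training minimizes cross-entropy on the normalized outputs by
full-batch gradient descent with classical momentum (defaults: learning
rate 0.05, momentum 0.9, at most 500 epochs — `metadann()` uses 300 —
patience-50 early stopping on validation accuracy with best-weight
restore). Full-batch descent keeps training deterministic under the
seed and avoids per-batch loops; a mini-batch size is available. With
roughly ten negatives per positive a plain fit collapses to the
majority class, so inverse-frequency class weights are the default.
Weights initialize from a symmetric Glorot-style uniform distribution;
analytic gradients are verified against central finite differences in
the test suite. Models serialize to JSON with 17 significant digits, so
a round trip reproduces forward outputs bit-exactly.

## Fitting pipeline

`metadann()` scales and routes the records, then per subset: holds out
a stratified 20% test split, tunes thresholds on the remaining 80%
(once per module, not per fold — thresholds precede network training in
the pipeline order; per-fold tuning is available by calling
`tune_thresholds()` directly), and cross-validates the network with
stratified folds — five when the training split has at least 1000
records, three otherwise (the split-count rule is size-based but the
published account does not state the boundary; 1000 is the package
default and configurable). Per-fold models and metrics are retained so
performance is reportable as mean ± s.d.; the deployed network is
retrained on the full training split. Subsets smaller than
`min_subset` (default 30) or with a single class are skipped and their
records return `NA` from `predict()`.

Duplicate records — identical availability masks with every shared
scaled score differing by less than 2% — are collapsed before
training. The 2% is interpreted on the scaled axis (|Δ| < 0.04, 2% of
the interval width), which makes the rule predictor-independent; which
member of a duplicate pair survives is decided uniformly at random
under the run seed via a seeded greedy pass, which also makes the
operation idempotent. Whether the comparison should cross availability
masks is moot here: subsets are disjoint by construction, so only
same-mask records are compared.

Two companion experiments mirror the training protocol:
`cross_subset_evaluate()` applies a module to records of a richer
pattern by projecting them onto the module's predictors, and
`merge_and_retrain()` concatenates such projected subsets (with
re-deduplication) and retrains the target module, reporting held-out
metrics split by subset of origin. Merging in the reverse direction
would require scores the source records lack and is an error.

## The synthetic generator

`simulate_interactions()` draws cohorts with the statistical structure
the method assumes, so every stage is testable without downloads:

* scores are truncated Gaussians on the scaled axis, mapped back to
  native ranges for output (miRDB high-is-better in the raw file);
  a unimodal shape is the simplest form consistent with smooth score
  densities, and a mixture of negative modes is available for
  spike-rich information-gain curves;
* negatives center at +0.3 with s.d. 0.25 — weak-interaction territory
  well inside the abstention bands of the default cutoffs;
* `positive_fraction` defaults to 0.08, the ~1:10 imbalance of curated
  interaction subsets;
* availability masks are drawn with probabilities proportional to the
  published non-redundant subset sizes, so D4 dominates and all eleven
  routable patterns occur;
* a `complementarity` fraction of positives (default 0.6) is detectable
  by exactly one of its present predictors — that predictor's score
  shifts by `effect_size` (default 0.9) toward −1 — while the rest
  carry an attenuated shift (`effect_size`/2) on every present
  predictor, modelling weak concordant evidence that only integration
  across predictors can use.

The generator emulates *score-level* structure only: no sequence
features, no per-miRNA or per-gene correlation, no batch structure
between subsets beyond their mask frequencies, and independent noise
across predictors. Passing tests therefore demonstrate that the
machinery is correct and that the ensemble logic extracts complementary
signal where it exists — not that any particular accuracy will be
attained on real score dumps.

## Numerical choices and problem sizes

Deterministic seeding covers every random step (splits, fold
assignment, duplicate survival, weight initialization, batch order);
identical seeds give byte-identical generator output and identical
fits. Grid construction, spike merging and candidate ordering in the
tuner are seed-free. Degenerate inputs fail loudly: single-class
training sets, unroutable records, mismatched feature widths and
negative confusion counts are errors; an all-one-class
information-gain curve warns and returns zeros; F1 with an empty
positive side warns and returns 0, and an MCC with a vanishing
denominator is 0 by convention.

The shipped tests run cohorts of 300–4000 simulated pairs, tree-oracle
grids of 441 exhaustive plus 2 × 2000 random points, 200-instance
entropy-oracle comparisons and 300-epoch network fits; the whole suite
completes in well under a minute, sizes chosen so the properties under
test (recovery, gain, calibration) are measured with margin rather
than at the edge of noise.

## Known limitations

* The eleven modules are independent; no information is shared across
  availability patterns unless `merge_and_retrain()` is used
  explicitly.
* Threshold tuning is a greedy coordinate search over spike candidates;
  it inherits the local character of that procedure and makes no
  global-optimality claim.
* The bounded-logit output compresses probabilities away from 0 and 1;
  ranking and 0.5-thresholded calls are unaffected, but the scores are
  not calibrated tail probabilities.
* Very small subsets (tens of records) train but with wide fold-to-fold
  variance; `summary()` exposes the s.d. so such modules can be judged.
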