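---
title: "Measure-guided multiple classifier systems for virtual screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measure-guided multiple classifier systems for virtual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Ligand-based virtual screening asks: given a few thousand compounds with
measured activity against a protein target, which members of a multi-million
compound vendor library are worth purchasing and assaying? Each compound is
described by a binary circular-fingerprint vector (e.g. 2048 FCFP_6-style
substructure bits) plus a few dozen physicochemical descriptors, and the
activity label is a binary cutoff on a potency scale (Active above a
potency threshold, Inactive below). The economics are asymmetric: a false
positive wastes an assay, a false negative loses a candidate. `mcscreen`
implements a screening architecture built around that asymmetry.

## The model

### Feature clustering

A single classifier over thousands of columns is unstable and opaque. The
multiple-classifier-system (MCS) approach instead partitions the *columns*
into `k` feature clusters and trains one specialist classifier per cluster.
`cluster_features()` scores each column by its Fisher score

$$F_j = \frac{(\mu_{A,j} - \mu_{I,j})^2}{\sigma^2_{A,j} + \sigma^2_{I,j}}$$

(population variances per class), then, within each feature type (binary
bits, discrete descriptors, continuous descriptors), sorts columns by score
and deals them round-robin into the `k` clusters. Every cluster therefore
receives a comparable mixture of strong and weak columns of every type and
is individually trainable. The default `k = 3` follows the reference
configuration of the workflow this package reimplements.

The published workflow delegates its multi-type Fisher clustering to an
external toolkit whose exact binning is not recoverable; the per-type
ranking + round-robin variant implemented here is *declared*, not inferred.
It preserves the two stated intents (multi-type handling, Fisher-guided
grouping) and adds a property we test: summed cluster scores differ
pairwise by at most the single largest column score. Perfectly separating
zero-variance columns get a configurable finite cap (default $10^6$) so the
sort stays total.

### Measure-guided classifier selection

For each cluster, `optimize_cluster_classifier()` grid-searches a roster of
classifier families by stratified cross-validation and keeps the candidate
maximizing a chosen objective:

* **MCC** (Matthews correlation coefficient) uses the whole confusion
  matrix and is robust to class imbalance; maximizing it balances false
  positives against false negatives.
* **PPV** (positive predictive value, $TP/(TP+FP)$) is the posterior
  probability that a predicted active is truly active — the quantity a
  purchasing decision cares about — but is degenerate in isolation: one
  lucky positive reaches PPV = 1. Two safeguards follow: PPV-optimized
  selection breaks near-ties (within $10^{-6}$) by cross-validated MCC, and
  the degenerate no-positive-prediction case returns 0 with a warning
  rather than an error.

Objective scores are computed on *pooled* out-of-fold predictions (one
confusion matrix over all folds) rather than averaged per fold; with PPV
and small folds, per-fold averaging is dominated by degenerate folds. The
cross-validation protocol (stratified, 5-fold by default) is our choice;
the source workflow does not state one.

**Roster.** The published system searches hundreds of classifiers across
dozens of families. That scale is neither practical nor necessary here, and
several families named in our build contract (random forests, boosted
trees, SVMs, decision trees) have no implementation in the frozen
dependency set this package targets. The default roster is therefore the
available probability-emitting families: regularized logistic regression
(ridge and lasso via glmnet), linear discriminant analysis, an authored
Bernoulli/Gaussian naive Bayes, and k-nearest neighbours with vote-fraction
probabilities. The roster is data, not architecture: any
`classifier_spec()` list can be passed to `build_mcs()`. Because every
default family natively emits an Active probability, the sigmoid
calibration wrapper foreseen for margin-only learners is unnecessary and
was not implemented.

### Voting and meta-models

`predict()` on an `mcs_model` records each inner classifier's Active
probability, thresholds at exactly 0.5 (Active iff $p > 0.5$), and combines
the inner labels by majority vote with ties going to Active — with an even
number of voters, a tie means half the experts see activity, and discarding
such a compound is the costlier error in discovery mode. A weighted scheme
(weights = cross-validated objective scores) is available.

Two measure-optimized models compose the meta-models of `combine_meta()`:

* `minimize_fp` — Active iff **both** the MCC- and PPV-optimized models say
  Active (logical AND). FP(AND) ≤ min of the constituents' FP, and TN(AND)
  ≥ max — these are theorems of the rule and the tests assert them exactly.
* `minimize_fn` — Active iff **either** model says Active (logical OR),
  with the dual guarantees on FN and TP.

The meta-rules vote over hard labels, not averaged probabilities; the
source describes the combination as "predicted Active by both/either",
which is a label-level statement.

### Probability-product ranking

Screening a large library leaves far more predicted actives than can be
assayed. Predicted actives are ranked by their global relevance

$$\Theta = \prod_i C_i$$

the product of all inner-classifier Active probabilities. The product
discriminates where linear aggregates cannot: the vectors
$[0.75, 0.75, 0.6]$ and $[0.6, 0.9, 0.6]$ share sum 2.1 and mean 0.7 but
yield $\Theta = 0.3375$ versus $0.324$. Design points:

* **Vector length.** For a meta-model over two k = 3 models the product
  runs over all six contributing inner classifiers. The worked example
  above uses a single model's three values; `global_relevance()` takes
  whatever vector `compile_probabilities()` hands it, so either convention
  is a matter of which prediction object is ranked.
* **Probabilities in (0, 1].** A compound can be voted Active while one
  inner probability is ≤ 0.5 (2-of-3 majority), so the ranking accepts any
  value in (0, 1]. Learner predictions are floored at $10^{-12}$ — a hard
  zero would annihilate the product for a compound other classifiers
  endorse.
* **Reporting.** $\Theta$ is kept at full precision; reports additionally
  show a 3-decimal truncated-toward-zero rendering (`trunc3()`), matching
  how such scores are conventionally printed (0.3375 → 0.337).
* **Ties** are broken by ascending compound id so purchasing lists are
  reproducible.

### Diversity selection

The top of the ranked list is structurally redundant — near-analogues score
alike. `leader_cluster()` runs single-pass sphere-exclusion clustering on
the fingerprint bits under a Tanimoto distance cap (default 0.35, forcing
within-cluster similarity to the center above 0.65), visiting compounds in
descending-Θ order so cluster centers are the most promising members; the
visit order of the original Pipeline-Pilot-based procedure is not
disclosed, and this choice makes `select_representatives()` — keep the
top-Θ member per cluster — coherent. The published "average cluster
population of 20" target is deliberately not enforced: the cap alone
determines cluster count (the source itself notes the cap dominates).
`diversity_stats()` reports mean ± sd pairwise Tanimoto distance within the
selection and mean ± sd distance to the nearest training compound. Two
all-zero fingerprints are defined as identical (similarity 1), a case
synthetic data can produce.

## The synthetic world

`generate_dataset()` emulates the real screening table's schema with a
controllable class-conditional signal:

| parameter | default | meaning |
|---|---|---|
| `n_active`, `n_inactive` | 500 / 500 | class sizes (near-balanced, like the curated training set) |
| `n_bits` | 256 | fingerprint width (reduced from 2048 so the pipeline runs in seconds; `paper_shape = TRUE` gives 2048/50/34) |
| `n_informative_bits` | 40 | bits that carry class signal |
| `p_active` / `p_inactive` | 0.8 / 0.2 | Bernoulli rates of informative bits per class |
| `background_rate` | 0.5 | noise-bit rate — matching frequency-selected fingerprints, which are chosen for ~50% occurrence |
| `discrete_shift` | +1 on a Poisson(5) | Active shift of discrete descriptors |
| `continuous_shift` | +0.5 sd | Active shift of continuous descriptors |

`generate_screening_library()` draws an unlabeled library from the same
generative model (same informative columns, derived deterministically from
the spec seed) at a chosen prevalence, with an exact-count mode for test
determinism. What the generator does **not** emulate: correlated bits from
shared substructures, analogue series, activity cliffs, assay noise, or
covariate shift between training set and vendor library. A green
parameter-recovery test therefore establishes that the pipeline recovers a
planted signal of stated strength — not that it would achieve any
particular hit rate on real chemistry.

## Numerical choices

* MCC returns 0 when any denominator marginal is zero (standard
  convention); the brute-force oracle (Pearson correlation of 0/1 label
  vectors) maps its undefined case to the same value.
* Fingerprint-bit selection (`select_bits_by_frequency()`) ranks by
  |frequency − target| with ties broken by ascending column index — the
  simplest rule consistent with avoiding both under- and
  over-representation; the alternative reading (a frequency band) has no
  stated width, so the closeness ranking was chosen.
* Row partitioning stratifies by class by default. The published 4-group
  split's class counts (504/478 in a group of 982) suggest a plain random
  split, but the split is described as homogeneous; stratification is the
  interpretation that guarantees it, and a flag disables it. Group sizes
  differ by at most one either way, and the seed is mandatory.
* The pipeline reuses group 2 for both feature clustering (groups 1–2) and
  model building (groups 2–3), reproducing the reference split; a
  configuration flag gives disjoint roles.
* Missing descriptor values are rejected at read time; the data dialect is
  UTF-8, tab-separated, header row, "." decimal separator, class encoded
  as `Active`/`Inactive`. Writes render doubles with 17 significant digits
  so read–write round-trips are bit-exact.

## Pharmacology utilities

Validation assays are processed with small, exact helpers: the
Cheng–Prusoff conversion $K_i = IC_{50} / (1 + [L]/K_D)$ (all
concentrations in nM at the interface), $pK_i = -\log_{10}(K_i \cdot
10^{-9})$, percent specific binding (total = 100%, nonspecific = 0%), a
displacement-percentage hit classifier (≥ 50% high, ≥ 25% medium,
configurable), and a hit-rate percentage.

## Known limitations

* The feature-clustering variant and cross-validation protocol are
  declared choices, not reconstructions of the original toolkit.
* The roster omits tree ensembles and SVMs (unavailable in the target
  dependency set); on real fingerprint data those families are often
  competitive, and the measured per-cluster scores should be read with
  that in mind.
* Leader clustering is $O(n \cdot c)$ in compounds × clusters with a dense
  similarity computation — fine for tens of thousands of predicted
  actives, not tuned for the full multi-million-compound library.
* The fingerprint adapter shells out to a Python RDKit; it is optional and
  nothing else depends on it.
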