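---
title: "Modularity-based feature subset selection: models, choices, limits"
author: "kfsgfs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modularity-based feature subset selection: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kfsgfs)
```

## The problem and the model

Univariate filter methods rank features one at a time, so they miss feature
groups that discriminate classes jointly while each member looks useless on
its own, and they happily keep redundant near-copies of a top-ranked
feature. `kfsgfs` scores whole candidate subsets instead, with a criterion
borrowed from network science.

Given a labeled dataset of m samples, a candidate subset S of features, and
a neighbor count K, the package builds the *sample graph in S*: nodes are
samples, and an undirected edge joins samples i and j when either is among
the other's K nearest neighbors under the Euclidean metric restricted to
the columns of S (`build_ksg()`). The quality of S is the Newman–Girvan
community modularity of this graph under the partition given by the class
labels — communities are the classes, never detected from the graph:

$$Q = \frac{1}{2e} \sum_{i,j}\Big[A_{ij} - \frac{d_i d_j}{2e}\Big]\,
      \delta(c_i, c_j)
    = \sum_c \Big[\frac{l_c}{e} - \Big(\frac{d_c}{2e}\Big)^2\Big],$$

where e is the number of undirected edges, $d_i$ node degrees, $l_c$ and
$d_c$ the within-community edge count and degree sum of class c. Q lies in
[-1, 1]; a high Q means same-class samples are mutual near neighbors in the
S-subspace and classes are sparsely interconnected — exactly the geometry a
nearest-neighbor classifier exploits. Both printed forms are implemented
(`modularity_pairwise()`, `modularity_community()`); they are algebraically
identical, and the test suite holds them to each other at 1e-12, with the
prefactor 1/(2e) on the pairwise form fixed by that equality.

Selection (`kfsgfs_select()`) is pure greedy forward search: step 1 keeps
the single feature with the largest 1-feature Q; every later step adds the
candidate f maximizing $Q_{S \cup \{f\}}$; the search stops at a preset
subset size P, with the Q history retained at every step so early-stopping
policies can be layered on later.

## Tunable parameters

* **K** (neighbor count, default 2). Small K keeps the graph sparse and the
  community signal local; the worked examples and defaults use K = 2, and
  values up to roughly 11 behave similarly on desk-scale data. K must be at
  most m − 1.
* **ties** (`"all"` or `"first"`, default `"all"`). How exact distance ties
  at the K-th neighbor rank are resolved; see the next section.
* **P** — the number of features to select; the search always runs to
  |S| = P.
* **base** (`"2"` or `"e"`) for the information diagnostics: bits by
  default, nats on request.
* **distance** (`"squared"` or `"plain"`, default squared) in the softmax
  exponent of the ENC diagnostic and in the k-means objective.

## The tie rule, and why it is the inclusive one

Low-precision measurements — one-decimal morphometrics, discretized
intensities — produce many exactly tied pairwise distances. Two
deterministic policies are implemented:

* `ties = "first"`: exactly K neighbors, ties broken by ascending sample
  index. Simple, but the resulting graph then depends on the arbitrary
  order in which samples happen to be stored: re-shuffling the rows of iris
  changes single-feature Q values by ~0.01 and can change the selection
  order.
* `ties = "all"` (default): every neighbor tied with the K-th nearest is
  admitted, so a neighborhood may exceed K. This is invariant to sample
  order, which we consider a requirement for a reproducible scientific
  result, and it is the only K = 2 Euclidean convention under which iris
  behaves canonically: petal length is the top single feature and the
  greedy order is petal length, petal width, sepal length, sepal width
  ({3, 4, 1, 2}).

The two rules coincide whenever all pairwise distances are distinct, so on
continuous synthetic data they give identical graphs.

## Preprocessing

`standardize()` centers each feature and scales by its *population*
standard deviation (divide by m), so that a 2-sample column [0, 2] maps
exactly to [-1, 1]; zero-variance columns become all-zero with a warning
rather than an error, keeping degenerate microarray columns loadable. The
transform is idempotent.

`discretize_nine_level()` maps a continuous feature to the alphabet
−4..4: the band within σ/2 of the mean (closed at both ends) becomes 0,
the four σ-wide intervals on each side become ±1..±4 (half-open away from
the center), and anything beyond is truncated to ±4. The σ here is again
the population form computed from the data being discretized, which makes
the rule invariant to prior standardization. This is the discretizer feeding
the information diagnostics below.

## Relevance diagnostics

`conditional_mi()` is the maximum-likelihood (plug-in) estimator on the
empirical contingency table, with the 0·log 0 = 0 convention; the estimate
is clamped at 0 against rounding. The *relevant independency* of a
candidate feature f against an already-selected feature g is
RI(f, C; g) = I(f; C | g): the class information f adds once g is known
(`ri_table()`). On nine-level-discretized iris conditioned on petal length,
petal width adds by far the most (RI ≈ 0.114 bits), then sepal length
(≈ 0.034), then sepal width (≈ 0.013) — the same ordering the modularity
score produces, which is the argument for using Q of the joint sample graph
as a practical surrogate for conditional-information bookkeeping, where
multivariate densities are hard to estimate. The absolute RI numbers do
depend on the discretizer and the log base; the ordering is stable across
every exposed combination.

## The clustering-side justification: ENC

`expected_correct_count()` connects a high Q to classifier geometry through
a stochastic nearest-neighbor model: sample i picks neighbor j with softmax
probability $P_{ij} \propto \exp(-\lVert x_i - x_j\rVert^2)$ (zero
diagonal, rows normalized over j ≠ i), is correctly classified with
probability $P_i = \sum_{j \in C_{t}, j \neq i} P_{ij}$, and
ENC = Σ P_i is the expected number of correctly classified samples;
ENIC = m − ENC exactly. Exponents are max-shifted per row before
exponentiation so microarray-scale distances cannot underflow. Feature
subsets with compact, well-separated classes attain both small k-means
objective J (`kmeans_objective()`, evaluation only — no Lloyd iterations)
and large ENC; empirically the single-feature ranking by Q and by ENC is
strongly rank-correlated on the synthetic benchmark (mean Spearman ρ ≈ 0.8
across seeds, recomputed by `scripts/acceptance.R`).

## Evaluation harness

`knn1_cross_val()` scores a subset by 1-nearest-neighbor accuracy under
k-fold cross-validation (default 10), averaged over several independent
runs (default 10) whose fold assignments re-randomize with run r seeded at
`seed + r`. Folds are stratified per class; when a class is smaller than
the fold count the harness falls back to plain random folds with a
warning. 1NN distance ties go to the lowest training index, so a report is
bit-reproducible from its seed. Accuracies are reported in percent.
`paired_one_tailed_t()` compares two methods' paired accuracy vectors with
the alternative mean(a − b) > 0, delegating to the standard t machinery
(df = pairs − 1); identically-zero-variance differences are an error, not
a p-value.

## The synthetic benchmark generator

`generate_synthetic()` realizes a `synthetic_spec()` with four feature
roles: XOR-like *group pairs* whose sign product carries the class parity
(each member sits at modes ±1 with Gaussian jitter, default sd 0.3, and is
marginally independent of the class), *informative* features with
unit-spaced class means and within-class sd 0.5, *redundant* near-copies
(jitter sd 0.1) of informative features, and standard-normal *noise*. The
defaults (150 samples/class, 2 classes, 1 pair + 3 informative +
2 redundant + 3 noise) exercise every role at a size where a full greedy
trace takes well under a second; these values were fixed once, before any
benchmark was run, as a plausible miniature of the redundancy and
group-structure found in expression data. What the generator does *not*
emulate: heavy-tailed intensity distributions, correlated noise across
features, batch effects, or class imbalance — passing the synthetic tests
says nothing about those regimes.

## What greedy search can and cannot recover

The benchmark makes one structural property of the method measurable.
The modularity *criterion* itself identifies group information: exhaustive
scoring of all two-feature subsets on XOR-pair-plus-noise data ranks the
pair first essentially always (the acceptance script reports this rate,
1.0 across seeds), and once one member of the pair is in S, the partner is
the next greedy pick by a wide margin. But the greedy *search* begins with
a univariate scan, and a feature whose marginal class signal is exactly
zero has a single-feature Q statistically indistinguishable from noise —
so whether the first pair member enters S before a noise feature is close
to a coin flip (the script reports this rate too, ~0.25). This is a
limitation shared by every forward search seeded from single-feature
scores, and it is the honest reading of the "group-discriminative"
claim: the criterion detects such groups; pure forward search only
completes them once one member is present. Users who suspect purely
group-informative pairs should seed the search with a pair scan
(`utils::combn` + `score_subset`) rather than rely on the univariate start.

## Numerical and degenerate-input choices

* Edgeless graphs raise an error ("modularity undefined") rather than
  returning Q = 0; a silent 0 would corrupt the argmax in selection.
* Score ties in the greedy argmax go to the lowest feature index
  (candidates are scanned in ascending order), making traces deterministic.
* A sample is never its own neighbor, and with m = 2, K = 1 the graph is
  the single possible edge.
* Q is invariant to any bijective relabeling of community codes, and a
  single-community partition gives exactly 0; both are property-tested.
* Per-candidate distances are recomputed naively per subset; results are
  therefore bit-identical to the definition, with no caching staleness.
* Problem sizes in the shipped tests and acceptance script — 150–500
  samples, ≤ 10 features, 20 benchmark seeds — keep a full run in the low
  minutes while leaving every assertion at its natural tolerance.

## Known limitations

Beyond the forward-search limitation above: modularity has a resolution
limit, so very small classes embedded in large graphs may not register as
communities (relevant for severely imbalanced data); brute-force O(m²)
graph construction is intended for desk-scale m, not for tens of
thousands of samples; and the evaluation harness deliberately ships only
1NN — any other classifier can be scored externally on the selected
subsets.
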