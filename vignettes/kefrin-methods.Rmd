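---
title: "Extended K-means for feature-rich networks: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended K-means for feature-rich networks: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kefrin)
```

## The model

A feature-rich network is a graph whose N nodes carry V-dimensional feature
vectors. We seek a partition into K communities that are simultaneously
cohesive in the link structure and homogeneous in the features. The package
takes a data-recovery view: the observed feature matrix `Y` and link matrix
`P` are approximated by rank-K indicator factorizations

\[
y_{iv} = \sum_k c_{kv} s_{ik} + f_{iv}, \qquad
p_{ij} = \sum_k \lambda_{kj} s_{ik} + e_{ij},
\]

where `s_ik` indicates membership of node *i* in community *k*, `c_k` is the
community's feature center, and `λ_k` is a *vector* of link intensities, one
per column of `P` — each node's links are allowed their own scale, so network
rows enter the model exactly like feature rows. Each community therefore has
a two-fold center `(c_k, λ_k)`, and minimizing the combined least-squares
criterion

\[
F = \rho \sum_{k}\sum_{i \in S_k} d(y_i, c_k) + \xi \sum_{k}\sum_{i \in S_k} d(p_i, \lambda_k)
\]

is a batch K-means problem in the concatenated space. Alternating
minimization applies: the Minimum Distance rule assigns each node to the
cluster with the smallest combined distance
`ρ d(y_i, c_k) + ξ d(p_i, λ_k)`; the center update replaces each `c_k`, `λ_k`
by within-cluster means; the loop stops when the partition repeats.

Three metrics are available for `d`:

* **squared Euclidean** — the criterion above literally; means are the
  optimal centers, so each half-step can only decrease F and the trajectory
  is provably non-increasing (a property the test suite asserts on every fit);
* **Manhattan** — `d(f,g) = Σ|f_t − g_t|`. Centers are still updated as
  means, which keeps the procedure a drop-in metric substitution but is a
  known theoretical mismatch: componentwise medians, not means, minimize the
  Manhattan criterion. We keep means as the default because the method is
  defined as the same algorithm with the metric substituted;
  `centers_fun = "median"` exposes the minimizing alternative;
* **cosine** — `d(f,g) = 1 − cos(f,g)`, intended for high-dimensional data.
  For unit vectors the squared Euclidean distance equals twice the cosine
  distance, so the cosine variant is spherical K-means on the two spaces:
  all data rows must be unit-normed (the pipeline does this) and centers are
  re-normed after every mean update. The re-norming breaks least-squares
  optimality of the centers, so the criterion is not guaranteed monotone and
  the loop may in principle cycle; see the safeguards below.

## Tunable parameters

* `rho`, `xi` (dimensionless, default 1 and 1): relative weights of the
  feature and network spaces. Equal weights are the documented default;
  automatic balancing is out of scope.
* `k`: the number of communities, fixed by the user. Selecting K from the
  data is deliberately not attempted.
* `n_init` (default 1 interactively, 10 in the benchmark harness): random
  restarts; the run with the smallest final criterion wins. Restarts matter
  because farthest-point seeding has a random first seed.
* `max_iter` (default 100): iteration cap. Convergence is declared on
  partition equality only — no criterion-epsilon stop, so converged runs stop
  in few iterations and the cap is a safety net.
* `feature_std` ∈ {`z`, `range`, `none`} and `network_std` ∈ {`modularity`,
  `shift`, `none`}: standardization operators. The default rule is z-scoring
  for features plus the modularity shift for links, switching to the scale
  shift whenever categorical features are present — the selection found to
  work best in the systematic standardization study the method comes with.

## Preprocessing choices

**One-hot encoding.** The criterion is numeric, but categorical features
arrive as labels. Each categorical column with m observed levels becomes m
0/1 dummies (`feature=level`), *before* standardization, so dummies are then
scaled like any numeric column. This is a documented package choice: the
method's description feeds categorical data to the numeric criterion without
fixing an encoding.

**Population standard deviation.** Z-scoring divides by the population (÷N)
standard deviation, the convention of the K-means / data-recovery literature.
Constant columns are an error, named in the message.

**Diagonal and asymmetry.** The link model runs over all (i, j) with no
exclusion, so the diagonal of `P` participates in network distances; matrices
are used as read, and a `directed` flag controls whether edge lists are
symmetrized. Seeds are taken from the *preprocessed* rows — standardization
precedes initialization in the algorithm.

## Numerical and algorithmic details

* **Tie-breaking** is everywhere "smallest index wins": in the Minimum
  Distance rule, in seeding, in the choice of repair node. This makes runs
  deterministic given the seed.
* **Empty-cluster repair.** Mean updates cannot handle an empty cluster. If
  a cluster empties during assignment, it is re-seeded from the node with the
  largest combined distance to its own current center (never a node that is
  the sole member of its cluster), mirroring the farthest-point seeding
  spirit. The repaired node has distance 0 to its new center, so the repair
  itself cannot increase the euclidean criterion, and every completed fit has
  exactly K nonempty clusters.
* **Cycle detection.** Because the cosine (and in principle Manhattan)
  variant lacks the monotone-criterion guarantee, the loop also stops when
  any previously visited partition recurs; such runs are flagged
  `converged = FALSE`.
* **Degenerate inputs.** K may not exceed N; a dataset whose rows are all
  identical cannot supply K distinct seeds and errors; zero rows under the
  cosine metric are assigned distance 1 to every center (cosine 0), a
  bounded, symmetric fallback.
* The node-to-center distance matrix — the only O(N·K·(N+V)) inner loop — is
  implemented in compiled code (RcppArmadillo); all algorithm logic stays in R.

## The synthetic generator

The generator emulates a planted-partition study design. Community sizes are
drawn by rejection (uniform cut points, every community ≥ `min_size`,
default 30, sizes summing to N). Edges are independent Bernoulli draws:
probability `p` within communities, `q` between. Quantitative features are
cluster Gaussians: center components uniform on `[−α, α]` (α is the intermix
dial — smaller α means more cluster overlap) and diagonal covariances with
variances uniform on `[0.05, 0.1]`. Categorical features draw their category
count per feature from `{2, …, L}`; planted centers are random category
picks, redrawn until no two centers agree on more than half the features; an
entry copies its planted center with probability ε and is uniform otherwise,
so larger ε means more homogeneous clusters, symmetric to the role of α.
Optional noise features replicate half the original column count with
uniform draws over the data's global range.

Benchmark presets follow two sizes: small (N = 200, K = 5, V = 5, L ≤ 10)
and medium (N = 1000, K = 10, V = 10, L ≤ 15). K and V per size are package
defaults, chosen as typical of planted-partition studies at these scales;
they are configurable, and benchmark means do depend on them.

What the generator does *not* emulate: degree heterogeneity (every node in a
community shares the same edge probabilities), overlapping communities,
weighted edges, feature correlations within clusters (covariances are
diagonal), and missing data. Recovery results on these synthetic grids
therefore say nothing about robustness to hubs, power-law degrees, or sparse
high-dimensional text features, all common in real attributed networks.

## Evaluation

Agreement with the planted truth is scored by the Adjusted Rand Index
computed from the contingency table (Hubert–Arabie form, all terms binomial
coefficients `C(·,2)`), which is 1 exactly at identity and 0 in expectation
under independence; a one-part partition scores 0 by convention. NMI is
provided as a secondary metric, normalized by the arithmetic mean of the two
label entropies (other normalizations exist; this one is fixed and
documented). Both are validated in the tests against independent
pair-counting oracles and reference implementations.

## Known limitations

* Manhattan centers are means by default (see above) — faithful to the
  procedure's definition, not to the Manhattan criterion.
* The combined space has dimension V + N, so the network block dominates the
  combined distance when N ≫ V unless `rho`/`xi` are rebalanced; the cosine
  variant mitigates, but does not remove, this.
* Dense N×N storage: adequate up to a few thousand nodes, not beyond.
* K, ρ, ξ are user inputs; no model selection is attempted.
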