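---
title: "Combinative hypergraph learning for miRNA-disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinative hypergraph learning for miRNA-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

MicroRNAs regulate gene expression post-transcriptionally, and their
deregulation is implicated in many human diseases. Confirmed miRNA-disease
associations are scarce relative to the space of possible pairs, so the
practical question is a ranking one: given a binary association matrix
`A` (`nm` miRNAs by `nd` diseases), a miRNA functional similarity `SM`,
and a disease hierarchy, which of the unknown pairs are most likely to be
real? `chlmda` answers it with a transductive model over engineered pair
features, using hypergraphs to capture the group structure among
miRNA-disease pairs that an ordinary graph (pairwise edges only) cannot
express.

## Similarity layer

**Disease semantic similarity.** Each disease is represented by its
ancestor-closed term set `T(d)` in the hierarchy. Two contribution models
assign weights to the terms of `T(d)`:

* frequency model: `D1(t) = -log(n_t / N)`, where `n_t` counts the disease
  DAGs containing `t` among the `N` diseases under study. Terms common to
  many diseases (e.g. near the root) contribute little; rare terms
  contribute much. The logarithm is natural; because the similarity is a
  ratio of sums of contributions, the choice of base cancels and is purely
  cosmetic.
* decay model: the disease's own term contributes 1, and every ancestor
  contributes `delta_sc` times the largest contribution among its children
  inside `T(d)`. The factor `delta_sc` (default 0.5, the customary value
  for this family of DAG-based measures) sets how fast relevance decays
  per generation; values near 1 flatten the hierarchy, values near 0
  reduce similarity to direct term overlap.

The similarity between diseases `i` and `j` under either model is the sum
of both diseases' contributions over the shared terms, divided by the sum
of their total semantic values; it is 1 on the diagonal and 0 for
diseases with disjoint DAGs. The working disease similarity `SD` is the
elementwise average of the two models' matrices, which hedges the
frequency model's insensitivity to depth against the decay model's
insensitivity to term rarity.

**Profile completion (WKNNP).** Gaussian interaction-profile kernels
computed directly from a sparse `A` understate the similarity of entities
whose associations are simply under-studied. Before the kernels are
computed, each zero of `A` is therefore estimated from the profiles of the
entity's `K` most similar neighbours (by `SM` for rows, `SD` for columns),
weighted by `decay^(rank-1) * similarity` with `K = 20` and
`decay = 0.8`; neighbour ties are broken by ascending index so the result
is deterministic. The row-side and column-side estimates are averaged and
the completed matrix is the elementwise maximum of that average with `A`,
clipped to `[0, 1]` — known associations stay at 1 and no entry ever
decreases. When fewer than `K` other entities exist, `K` is truncated
with a warning.

**Kernels and fusion.** The Gipk bandwidth is one over the mean squared
profile norm, so the kernel adapts to matrix density. Fusion is
zero-aware: where the base similarity is exactly 0 (absence of evidence,
not evidence of dissimilarity) the kernel value is used alone; elsewhere
the two are averaged. The order of operations is semantic/functional
similarity first, then WKNNP, then the kernels, then fusion — the kernels
must see the completed matrix, and WKNNP needs a similarity that does not
itself depend on the completion.

## Pair features

Each pair is described by 66 numbers (defaults):

* type 1 (statistical, 7 per entity): association count, mean similarity
  to the other entities (self excluded — the self-similarity is a
  constant 1 and carries no information), and a 5-bin histogram of those
  similarities. The bins partition `[0, 1]` with equal width, right-open
  except the last; a fixed global range keeps the feature comparable
  across entities.
* type 2 (graph-theoretic, 23 per entity): degree, the 20 largest
  neighbour similarities (descending, zero-padded), normalised
  betweenness, and closeness in the similarity graph that links two
  entities when their similarity strictly exceeds the mean off-diagonal
  similarity. Closeness uses the component-scaled (Wasserman-Faust) form
  `(k/(n-1)) * (k / sum of distances to the k reachable vertices)`, with
  0 for isolated vertices, so disconnected graphs are well-defined.
* type 3 (cross, 6 per pair): the number of associations between the
  miRNA and the disease's similarity-graph neighbours, the symmetric
  count for the disease, and betweenness/closeness of both the miRNA node
  and the disease node in the bipartite association graph. Computing both
  nodes' centralities (4 values) retains strictly more information than
  either alone.

Feature columns are z-scored with statistics computed from the training
rows only; scoring applies the stored training statistics to query rows.
Standardisation matters because Euclidean distances on the raw scale
would be dominated by the count-valued features, and computing it from
training rows only is required for leakage-free evaluation.
Zero-variance columns are centred but given unit scale.

## Hypergraphs and the learner

Two complementary hypergraph views are built over the standardized
training rows. The KNN view has one hyperedge per vertex — the vertex and
its `k1` nearest neighbours (Euclidean; ties by index) — weighted by the
sum of Gaussian affinities `exp(-||x_v - x_u||^2 / sigma^2)` between the
centroid and its neighbours, where `sigma` is the mean squared dispersion
of the rows about their centroid (with an `n-1` denominator). The
centroid's self-affinity is excluded from the weight: it would add a
constant 1 to every hyperedge and carry no information. The K-means view
partitions the vertices into `k2` clusters (10 restarts, 300-iteration
cap, fixed seed; clustering details are otherwise immaterial to the
model) with equal hyperedge weights `1/n_e`; empty clusters are dropped
with a warning, and `k2` is capped at the number of distinct rows.
Defaults `k1 = 20`, `k2 = 100` sit on the plateau where the method is
insensitive to either value.

For each view the projection `P_i` solves the Laplacian-regularised ridge
problem in closed form (a symmetric positive-definite solve, never an
explicit inverse; `mu > 0` guarantees definiteness, and the stationarity
residual is checked to 1e-8). The combination weights minimise
`sum_i beta_i Theta_i + eta ||B||^2` on the probability simplex; the
stationarity formula is used directly when it is feasible, and otherwise
the weights are Euclidean-projected onto the simplex — for this quadratic
objective the projection of the stationarity solution *is* the
constrained minimiser, which the tests confirm against a grid search. The
per-view projections are learned independently and the weights second;
the weights do not feed back into the projections. Larger `eta` shrinks
the weights toward (0.5, 0.5); the default `eta = 1000` with `lambda = 10`
and `mu = 1` gives stable behaviour over wide parameter ranges.

The scalar ranking score is the positive-class column of `x P` minus the
negative-class column — a monotone transform of the positive column alone
whenever the label rows are one-hot, but antisymmetric in the two columns
and hence insensitive to a constant shift in both.

## Evaluation protocol

Cross-validation masks the held-out associations *before* anything else:
WKNNP, the kernels, fusion, the features, the negative sample, and the
standardisation statistics are all recomputed from the masked matrix in
every fold. Negatives are resampled per fold with a fold-derived seed, and
masked test positives are excluded from the negative pool. The k-fold
driver pools test and candidate scores across the folds of a repeat into
one rank AUC (Mann-Whitney with half credit for ties) and reports mean and
standard deviation over repeats; the LOOCV driver ranks each held-out
positive against all unknown candidate pairs and averages the
per-positive AUCs. Both drivers accept a pluggable scorer so that oracle
and random baselines run through the identical protocol. The ablation
driver repeats k-fold on each of the seven non-empty subsets of the three
feature families.

## Synthetic study data

The generator plants the latent structure that every similarity the
method exploits is a proxy for: sparse non-negative factors `U` (miRNAs)
and `V` (diseases), each row loading on one primary factor plus occasional
weak secondary loadings; `U V'` thresholded at the quantile matching the
target density; entries flipped with the noise probability. The miRNA
similarity is the cosine similarity of the `U` rows, and the disease
hierarchy is a rooted tree whose recursive splits follow K-means clusters
of `V`, so hierarchy proximity tracks factor proximity. The reference
conditions are 60 miRNAs, 40 diseases, rank 3, 8% density, 2% noise — a
scale at which strict per-fold recomputation of the whole pipeline stays
comfortably fast (a full 5-fold run takes a few seconds) while leaving
roughly 230 positives, enough for stable fold AUCs. The compact LOOCV
example uses 20 x 15 at rank 2 for the same reason.

What the generator does *not* emulate: the heavy-tailed degree
distribution of curated association databases, the depth and fan-out of a
real disease taxonomy, and literature-driven correlation between an
entity's study intensity and its association count. Passing tests
therefore demonstrate that the machinery recovers planted low-rank
structure under leakage-free evaluation — not any particular performance
level on curated data.

## Numerical and degenerate-input choices

* Similarity matrices are symmetrised as `(M + M')/2` when the asymmetry
  is at most 1e-8 and rejected otherwise; stored matrices are exactly
  symmetric.
* All-zero interaction profiles make the Gipk bandwidth undefined and
  raise an error, as does a feature matrix with identical rows (degenerate
  kernel scale) and a hypergraph with an isolated, zero-degree vertex.
* WKNNP neighbourhoods with all-zero similarity weights contribute an
  estimate of 0 rather than 0/0.
* `kmeans` can return fewer effective clusters than requested; empty
  clusters are dropped and the equal weights renormalised.
* The whole pipeline is deterministic given the configuration seeds:
  every stochastic step (negative sampling, fold assignment, clustering
  restarts) draws from an explicit seed and restores the caller's RNG
  state.

## Limitations

The model is linear in the engineered features; interactions beyond those
hard-coded in the type-3 features are only captured through the
hypergraph regulariser. Exactly two hypergraph views are exposed (the
internal machinery generalises, but the combination-weight formula is
two-view in spirit). LOOCV retrains the full pipeline once per known
association and is only practical at desk scale; for large matrices the
k-fold driver is the realistic protocol. Disease terms absent from the
hierarchy cannot be scored, and identifier matching across input files is
by exact string.
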