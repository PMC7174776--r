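# chlmda

Multi-similarity combinative hypergraph learning for miRNA–disease
association prediction.

Experimentally confirmed miRNA–disease associations are sparse: for most
(miRNA, disease) pairs it is unknown whether the miRNA is involved in the
disease. `chlmda` ranks the unknown pairs by how likely they are to be true
associations, for researchers prioritising candidate miRNAs for
experimental follow-up. It takes three inputs: a binary association matrix
`A` (nm miRNAs × nd diseases), a miRNA functional similarity matrix `SM`,
and a MeSH-like disease hierarchy from which per-disease DAGs are derived.

## Method

**Similarities.** Disease semantic similarity is the normalised overlap of
ancestor contributions between two disease DAGs, under two contribution
models: a frequency model, `D1(t) = −log(n_t / N)` with `n_t` the number of
disease DAGs containing term `t`, and a decay model in which a disease's
own term contributes 1 and each ancestor contributes `Δ` times its best
child (Δ = 0.5 by default). The two matrices are averaged into `SD`. The
association matrix is then completed by weighted K-nearest-neighbour
profiles (WKNNP): zeros are replaced by decay-weighted averages of the
profiles of the most similar miRNAs (rows) and diseases (columns). From the
completed matrix, Gaussian interaction-profile kernels are computed,

    GIM(i, j) = exp(−γ_m ‖KS(m_i) − KS(m_j)‖²),   γ_m = 1 / mean‖KS(m)‖²,

and fused with the base similarities: where `SM` (or `SD`) is zero the
kernel value is used alone, elsewhere the two are averaged, giving the
multi-similarity matrices `MMS` and `DMS`.

**Features.** Each (miRNA, disease) pair gets a 66-dimensional feature
vector: statistical summaries of `A`, `MMS`, `DMS` (association counts,
mean similarity, a 5-bin similarity histogram; type 1), graph-theoretic
descriptors of the thresholded similarity graphs (degree, top-20 neighbour
similarities, betweenness, closeness; type 2), and cross features coupling
the pair through the association matrix and the bipartite association
graph (type 3).

**Learning.** Two hypergraphs are built over the training pairs: a KNN
hypergraph (each vertex plus its k₁ = 20 nearest neighbours, hyperedges
weighted by summed Gaussian affinities) and a K-means hypergraph (k₂ = 100
clusters, equal weights). For each view `i` the projection matrix

    P_i = λ (XᵀΔ_iX + λXᵀX + μI)⁻¹ XᵀY

minimises the hypergraph-Laplacian-regularised ridge objective
`tr(PᵀXᵀΔXP) + λ‖XP − Y‖² + μ‖P‖²` in closed form, with
`Δ = I − Dv^{−1/2} H W De^{−1} Hᵀ Dv^{−1/2}`. The views are combined by
simplex weights `β_i = 1/2 + ΣΘ/(4η) − Θ_i/(2η)` (projected onto the
simplex if negative), where `Θ_i` is view i's objective value. A query pair
scores `S(x) = Σ_i β_i x P_i`, ranked by the positive-minus-negative column
difference. Defaults λ = 10, μ = 1, η = 1000.

Evaluation follows a strict protocol: in every cross-validation fold the
held-out associations are zeroed *before* WKNNP, the kernels, the features
and the standardisation statistics are recomputed, so no held-out
information leaks into training.

## Worked example

Everything is runnable without external databases via the built-in
synthetic generator, which plants low-rank structure that all three
similarity sources reflect:

```r
library(chlmda)
ds <- simulate_dataset(synth_config())       # 60 miRNAs x 40 diseases
ds$A
#> association_matrix: 60 miRNAs x 40 diseases, 231 known links

sims <- multi_similarity(ds$A, ds$SM, ds$dag)
sims$MMS
#> similarity_matrix [MMS]: 60 entities, mean off-diagonal 0.4139

pos <- positive_pairs(ds$A)
neg <- sample_negatives(ds$A, nrow(pos), feature_config(rng_seed = 1))
ft  <- assemble_pair_features(ds$A, sims$MMS, sims$DMS, feature_config(),
                              rbind(pos, neg))
ft
#> pair_feature_table: 462 pairs x 66 features (231 positive)

model <- train_chl(ft, hypergraph_config(k1 = 20, k2 = 100), chl_config())
model
#> chl_model: 2 views, beta = (0.492, 0.508), theta = (3.13e+03, 3.1e+03)

kfold_cv(ds$A, ds$SM, ds$dag, pipeline_config(), k = 5, repeats = 5,
         seed = 0)
#> cv_result [kfold]: mean AUC 0.8921 (sd 0.0041) over 5 value(s)
```

The mean AUC near 0.89 — against a 0.5 chance level — shows the pipeline
recovering the planted association structure from the masked training
folds alone. `beta` close to (0.5, 0.5) means the two hypergraph views fit
the training data about equally well.

A command-line front end wrapping the same functions (subcommands
`simulate`, `similarity`, `featurize`, `train`, `predict`, `cv`,
`ablation`) is installed at
`system.file("scripts/chlmda-cli.R", package = "chlmda")`.

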