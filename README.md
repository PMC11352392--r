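# idhypergraph

Subtyping of a patient cohort from regional brain-activity features by
**individual-deviation hypergraph clustering**.

Unsupervised subtyping of heterogeneous conditions (the package's motivating
use case is resting-state fMRI ALFF in autism spectrum disorder) usually
clusters patients by pairwise similarity computed from patient data alone.
This package implements an alternative that (a) represents every patient
relative to the *control* population, and (b) connects patients by
*higher-order* relationships rather than pairwise edges:

1. **Inter-individual deviation.** Each case subject *i* with regional
   feature vector `F_i` is encoded by its cosine distance to every control
   subject *j*: `X[i, j] = 1 − (F_i · F_j) / (‖F_i‖ ‖F_j‖)`, giving an
   `n × m` deviation matrix `X` (cases × controls).
2. **Elastic-net hyperedges.** Each case's deviation profile `x_i` is
   regressed on all other cases' profiles,
   `min_w ‖x_i − X_{−i} w‖² + λ₁‖w‖₁ + λ₂‖w‖₂²`,
   and the hyperedge of centroid *i* is `{i} ∪ support(w)`. Aggregating one
   hyperedge per case gives the ID-Hypergraph with incidence matrix
   `H ∈ {0,1}^{n×n}` (unit diagonal, identity weight matrix).
3. **Hypergraph community detection.** Subtypes are the partition `Z`
   maximizing the symmetric hypergraph modularity
   `Q(Z) = − Σ_k [ β_k cut_k(Z) + γ_k Σ_C vol(C)^k ]`,
   where `cut_k` is the multiplicity mass of size-`k` hyperedges straddling
   clusters and `vol(C)` the degree volume of cluster `C`. `Q` is maximized
   by a Louvain-style coordinate ascent (seeded restarts, single-vertex
   moves, hyperedge-collapse and cluster-merge proposals), optionally
   alternating with maximum-likelihood-style estimation of `(β_k, γ_k)`.
   The number of subtypes is not an input; it emerges from the argmax.
4. **Evaluation.** Subtype separability by one-vs-one RBF-SVM with
   stratified 10-fold cross-validation (ACC/SEN/SPE from the pooled
   out-of-fold confusion table, AUC by rank statistic), and per-subtype
   regional difference maps against controls via covariate-adjusted linear
   models with Benjamini–Hochberg FDR control.

A synthetic-cohort generator (planted subtypes as region-block mean shifts,
additive site effects, ages, ADOS-like clinical scores) and a
planted-partition hypergraph generator make every stage testable without
clinical data.

## Worked example

```r
library(idhypergraph)

cfg <- cohort_config(n_case = 60, n_control = 50, n_features = 60,
                     n_subtypes = 3, regions_per_subtype = 12,
                     effect_size = 3, seed = 42)
sim <- simulate_cohort(cfg)
sim$features
#> feature_table: 110 subjects x 60 features (60 case / 50 control)

run <- run_pipeline(as_run_config(list(seed = 7, log_level = "quiet",
                                       hmll = list(n_restarts = 10),
                                       svm = list(n_folds = 5))),
                    features = sim$features)
run$partition
#> hg_partition: 60 vertices in 3 clusters, Q = -95.75233
#> cluster sizes: 20, 20, 20
adjusted_rand_index(sim$truth, run$partition$labels)
#> [1] 1
run$svm$pairs[, c("pair", "acc", "sen", "spe", "auc", "C")]
#>    pair acc sen spe auc      C
#>  1 vs 2   1   1   1   1 0.0312
#>  1 vs 3   1   1   1   1 0.0312
#>  2 vs 3   1   1   1   1 0.0312
which(run$profiles$subtype1$significant)
#>  [1]  1  2  3  4  5  6  7  8  9 10 11 12
```

The three planted subtypes are recovered exactly (ARI 1), every subtype pair
is perfectly separable out-of-fold, and subtype 1's difference map flags
exactly its planted 12-region block.

With an `output` path in the config, `run_pipeline()` also writes the
deviation matrix, the hypergraph (plain-text edge list), the partition
(CSV + JSON with `Q`, parameters and seeds), the SVM metrics table, the
per-subtype difference maps, and a frozen config enabling bit-identical
re-runs; `replicate_run()` applies a frozen config to a second cohort
without re-selecting any penalty or modularity parameter.

A command-line front end covering each stage
(`simulate | deviation | build-hypergraph | cluster | evaluate | stats |
pipeline | replicate`) is installed at `inst/cli/idhg`.

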