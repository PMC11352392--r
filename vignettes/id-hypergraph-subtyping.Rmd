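---
title: "Individual-deviation hypergraph subtyping: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-deviation hypergraph subtyping: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idhypergraph)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the places where the design was genuinely open and we had to decide.

## 1. The model

### Deviation encoding

Every case subject is represented not by its raw regional feature vector
(mean ALFF per atlas region in the motivating application) but by its vector
of cosine distances to every control subject,
$$X_{ij} = 1 - \frac{F_i \cdot F_j}{\lVert F_i\rVert \lVert F_j\rVert},
\qquad X \in [0,2]^{n \times m}.$$
The encoding imports diagnostic information from the control group: two
cases are similar when they deviate from the *same controls in the same
way*. Cosine distance is scale-invariant per subject, so multiplicative
differences in overall signal amplitude cancel. We deliberately do **not**
centre the vectors (that would be correlation distance; available behind
`distance = "correlation"`) and do not z-score features against controls by
default (`zscore_controls = FALSE`): both switches exist, both default to
the plain cosine reading of the construction.

An important consequence, visible in the synthetic cohorts: whatever
variation is *common* to all subjects (a shared regional baseline) drives
all deviation profiles toward strong mutual correlation. The subtype signal
lives in the smaller orthogonal component. Downstream steps must cope with
nearly collinear profiles, which shaped the solver choice (Section 4).

### Hyperedges by sparse self-representation

Each case's profile is regressed on all other cases' profiles with an
elastic net (no intercept; predictors scaled to unit norm by default):
$$\min_w \lVert x_i - X_{-i} w\rVert^2 + \lambda_1 \lVert w\rVert_1
 + \lambda_2 \lVert w\rVert_2^2 .$$
The hyperedge of centroid $i$ is $\{i\} \cup \operatorname{supp}(w)$; one
hyperedge per case, unit weights, gives the ID-Hypergraph (incidence matrix
$H \in \{0,1\}^{n\times n}$ with unit diagonal). The $\ell_2$ term provides
the grouping effect — exactly duplicated predictors provably receive equal
coefficients — so clusters of mutually similar cases are selected together
rather than one-of-many as the lasso would.

### Symmetric hypergraph modularity

Subtypes are the partition $Z$ maximizing
$$Q(Z) = -\sum_{k=1}^{\bar k}\Bigl[\beta_k\, \mathrm{cut}_k(Z)
 + \gamma_k \sum_{C} \mathrm{vol}(C)^k\Bigr],$$
with $\mathrm{cut}_k$ the multiplicity mass of size-$k$ hyperedges whose
vertices span two or more clusters (an *all-or-nothing* notion: an edge
only rewards a partition once all its vertices share a label) and
$\mathrm{vol}(C)$ the degree volume of cluster $C$. $\beta_k$ prices cut
edges; $\gamma_k$ rents volume and thereby controls cluster sizes. The sign
convention keeps both terms negative and maximizes; equivalent formulations
differ by partition-independent constants that leave the argmax unchanged.

The number of clusters is never an input: it emerges from the maximization.

## 2. Parameters that matter

| parameter | default | units / range | why this default |
|---|---|---|---|
| `lambda1` (per centroid) | `0.65 * lambda_max` | fraction of the KKT bound | see Section 5; supports of median size ≈ `1.5 log n` |
| `lambda2` | 0.01 | absolute | activates grouping without densifying the fit |
| `n_folds` (CV mode) | 10 | folds over the `m` deviation features | conventional ten-fold split |
| `beta_k` default | 1 | per edge size | neutral cut price |
| `gamma_k` default | `m_k k / vol(V)^k` | per edge size | planted-partition-style resolution, scale-matched to the cut term |
| `n_restarts` | 20 | — | seeded multistart of a non-convex ascent |
| `tol` | 1e-10 | modularity gain | strict-improvement move acceptance |
| SVM `C` grid | `2^-5 … 2^2` | — | conventional powers-of-two sweep |
| RBF `gamma` | `1/(p · pooled var)` | — | the classical bandwidth heuristic |
| FDR level | 0.05 | per comparison | convention; applied across features within each map |

## 3. The synthetic world

`simulate_cohort()` emulates a two-group, multi-site regional-activity
cohort at typical multi-site scales (on the order of 150 cases and 125
controls per dataset): per-region Gaussian baselines with means in `[0.8, 1.2]`
(the scale of normalized regional ALFF), subject noise `noise_sd = 0.1`,
`K = 4` planted subtypes each shifting a disjoint 20-region block by
`effect_size × noise_sd`, additive per-site regional offsets
(`SD = noise_sd/2`, shared by cases and controls, so site is a genuine
nuisance for clustering and a meaningful covariate for the statistics),
uniform ages, and ADOS-like scores with a mild subtype dependence in the
communication domain.

What a green test on this world establishes: that the chain
deviation → elastic-net hyperedges → modularity ascent can recover
block-shift subtypes through realistic site nuisance, and that the
evaluation stack is calibrated (FDR under the null, chance-level SVM under
permuted labels). What it does not establish: anything about real fMRI
spatial autocorrelation, heavy-tailed site effects of real multi-site
repositories, covariance-based (rather than mean-shift) subtype signals, or
clinical validity of subtypes.

## 4. Numerical choices

* **Elastic-net solver.** Deviation profiles are nearly collinear
  (Section 1), which makes plain coordinate descent converge at a crawling
  linear rate. The production solver is an active-set *feature-sign search*:
  exact solves of the restricted system
  $(G_{AA} + \lambda_2 I) w_A = q_A - \tfrac{\lambda_1}{2}\theta_A$ with an
  incrementally extended Cholesky factor, sign-crossing line searches with
  guaranteed descent, and termination only when the full KKT conditions
  hold. Off-support zeros are exact, so the support threshold is 0. A plain
  coordinate-descent kernel is retained internally and the two are held to
  machine-precision agreement in the tests; an `optim()`-based
  split-variable solver serves as the independent oracle.
* **Volume powers.** `vol(C)^k` overflows doubles quickly. The exported
  `volume_term()` uses exact integer arithmetic up to $2^{53}$ and a small
  internal big-integer representation beyond, rounding once on return. The
  ascent itself works in normalized coordinates — volume fractions
  $\rho_C = \mathrm{vol}(C)/\mathrm{vol}(V)$ against scaled coefficients
  $\tilde\gamma_k = \gamma_k \mathrm{vol}(V)^k$ — which cannot overflow at
  any edge size.
* **Tie-breaking.** A vertex moves only for a strict gain (`dq > tol`);
  among tied targets the lowest label wins; vertex order within a sweep is
  a seeded shuffle; all randomness flows through R's RNG so every result is
  reproducible from its seed.
* **Degenerate inputs.** Zero-norm feature vectors, non-finite values,
  empty hyperedges, rank-deficient designs (e.g. site confounded with
  group) and undefined metrics (empty positive class) are hard errors that
  name the offending subject, column or metric — never silent `NaN`s.

## 5. Where the design was open, and what we chose

**Sparsity selection.** Two selection policies are in common use for
$\lambda_1$ in sparse-representation hypergraphs — a CV grid search and a
fixed sparsity parameter — and here they are not interchangeable. Minimizing out-of-fold
prediction error on nearly collinear profiles *always* selects the densest
grid point (better self-prediction), yet hyperedges of 30+ members are
worthless to an all-or-nothing modularity: one impure member makes the edge
a cut edge under the true partition, so the partition signal vanishes.
`select_lambdas()` therefore implements the CV contract faithfully (and is
tested against it), while the pipeline default is the fixed-sparsity rule
`lambda1 = 0.65 * lambda_max` per centroid: each subject keeps its natural
support at a common relative penalty, with median hyperedge sizes near
`1.5 log n` — above the connectivity threshold of a random neighbor
hypergraph (which needs on the order of `log n` peers per vertex) and small
enough to stay nearly pure. The constant was fixed once during development
on synthetic cohorts and is a config knob (`elastic_net$lambda1_frac`).

**Composite moves.** With all-or-nothing edges of size ≥ 3, no sequence of
single-vertex moves from the all-singleton start can ever make an edge
interior: the first step is pure volume penalty. The ascent therefore
interleaves two composite proposals, each accepted only on an exact
modularity gain: *edge collapses* (relabel an entire straddling hyperedge
into one cluster) and *cluster merges* (fuse two clusters connected by
straddling edges — the Louvain aggregation step expressed on the flat
partition, without which the ascent stalls in fragmented local optima whose
sub-clusters no single move can fuse).

**Parameter estimation.** In `params = "estimate"` mode the ascent
alternates with a method-of-moments update
($\beta_k = \log(\hat\omega_{in}/\hat\omega_{out})$,
$\gamma_k = \hat\omega_{in} - \hat\omega_{out}$, rates floored so estimates
are never infinite). Two safeguards matter. First, each alternation
re-solves the partition from scratch: an incremental update can neither
split a wrongly fused cluster nor escape the enormous volume penalties that
a fine partition induces in the re-estimated $\gamma_k$. Second, the
iteration keeps whichever partition scores better under the *current*
parameters, and stops when the re-solve stops improving — the naive fixed
point runs away to over-split partitions that justify ever-larger
$\gamma_k$. Across restarts the winner is the consensus medoid (largest
mean pairwise adjusted Rand index), because modularity values under
restart-specific estimated parameters are not mutually comparable; with
fixed parameters the plain argmax-Q is used.

**Replication mode.** A frozen run stores the selected penalty pair, the
final $(\beta_k, \tilde\gamma_k)$ and the discovery volume.
`replicate_run()` reuses them verbatim — no grid search, no estimation —
rescaling $\tilde\gamma_k$ to the replication graph's volume in log space
and falling back to defaults for edge sizes the discovery graph never
produced.

**Evaluation conventions.** The positive class of a subtype pair is the
lower-numbered subtype (SEN/SPE depend on the choice, so a documented
convention is required);
metrics come from the pooled out-of-fold confusion table; `C` is chosen by
pooled out-of-fold accuracy over the same single ten-fold loop (no nested
CV); the multi-class summary is the unweighted mean over pairs. With no
covariates the group test is exactly the classical equal-variance
two-sample t-test; with covariates it is the group coefficient's t in
`value ~ group + covariates`, which is the only coherent reading of a
"t-test with covariates". FDR is controlled per difference map, not across
maps.

## 6. Known limitations

* On synthetic cohorts with realistic site nuisance, the modularity's own
  optimum does not always coincide with the planted partition: blocks whose
  hyperedge sets are internally disconnected (a k-nearest-peer phenomenon)
  are genuinely preferred split, and blocks linked by a few impure bridge
  edges can be preferred fused. The package's tests quantify this honestly:
  recovery is strong but the returned cluster count frequently exceeds the
  planted count by one or two sizeable sub-communities. This is a property
  of the objective family, verified by ascents run under parameters
  estimated at the true partition, not a search deficiency.
* The alternating estimation has many fixed points; the consensus-medoid
  selection is a heuristic, and a minority of restarts may hold a strictly
  better partition.
* The elastic-net stage treats deviation features as exchangeable samples
  for cross-validation; spatially correlated atlases violate that mildly.
* No site harmonization is applied before the deviation encoding (the
  construction is silent on it); site enters only as a covariate in the
  statistics.
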