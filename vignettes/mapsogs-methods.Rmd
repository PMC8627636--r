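---
title: "Graph-guided many-objective gene selection: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-guided many-objective gene selection: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Expression studies in medical diagnosis routinely measure thousands of genes
on a few dozen samples. Most genes are irrelevant to the class of interest,
and many of the relevant ones are redundant copies of the same co-expression
signal. A gene selector for this regime has to do two different jobs at once:
drop genes that carry no class information (irrelevance) and avoid selecting
several genes that carry the *same* information (redundancy), while keeping
the subset small enough to be interpretable.

`mapsogs()` implements a hybrid filter–wrapper strategy built around a gene
co-expression graph:

1. **Filter.** Rank genes by Fisher score and keep the top `m` (or all genes
   scoring at least `lambda`).
2. **Graph.** Connect the kept genes with absolute Pearson correlation as
   edge weight, squash the weights through a logistic function centred on
   their mean, and drop edges below `theta`.
3. **Cluster.** Partition the graph with Louvain modularity optimisation;
   each cluster is a group of mutually co-expressed genes.
4. **Search.** Run a binary particle swarm over selection masks, comparing
   candidates by Pareto dominance on five minimised objectives, with a
   repair operator that keeps every cluster represented.

## The scoring and graph model

The Fisher score of gene $g$ is
$$\mathrm{Score}(g) = \frac{\sum_k n_k(\bar g_k - \bar g)^2}{\sum_k n_k \sigma_k^2},$$
with class sizes $n_k$, class means $\bar g_k$, overall mean $\bar g$ and
*population* class variances $\sigma_k^2$ (the $n_k$ weighting makes the
population form the consistent choice). Two degenerate cases are pinned
down so behaviour is deterministic on small samples: a constant gene
(0/0) scores 0, and a gene whose classes are internally constant but
separated (positive over zero) is capped at the sentinel `1e12`. Scores are
min–max normalised to $[0,1]$ for use as per-gene selection probabilities;
if all scores are equal every gene maps to 0.5.

Edge weights start as $w_{ij} = |\mathrm{cor}(g_i, g_j)|$; a zero-variance
gene gets similarity 0 to everything. The logistic rescaling
$\hat w_{ij} = 1/(1 + e^{-(w_{ij}-\bar w)/\sigma})$ uses the mean and
standard deviation over all unordered pairs, is strictly order-preserving,
and maps everything to 0.5 when $\sigma = 0$. Thresholding keeps edges with
$\hat w \ge \theta$ and never removes nodes.

Two centralities feed the objectives. Node centrality defaults to weighted
eigenvector centrality (max-normalised, isolated nodes 0) with strength as
the fallback when the eigen-iteration fails; it rewards subsets containing
influential, representative genes. Edge centrality defaults to the
normalised edge weight itself, which turns the summed edge centrality of a
subset into a direct redundancy penalty; weighted edge betweenness
(distances $1/\hat w$, normalised by the number of node pairs) is available
for users who prefer a path-based notion of relational intensity. Both
centralities are computed once, on the thresholded graph, before the swarm
loop — objectives must be cheap and stable inside the search.

## Louvain and the modularity gain

Clustering maximises weighted Newman–Girvan modularity with the standard
two-phase Louvain scheme: seeded-shuffle local moves, then aggregation,
repeated to a fixed point. The insertion gain used in the local phase is
$$\Delta Q = \frac{k_{i,\mathrm{in}}}{m} -
  \frac{\Sigma_\mathrm{tot}\, k_i}{2m^2},$$
which is exactly the modularity difference between "node in cluster" and
"node as singleton"; the published bracket form of this gain reduces to the
same expression once the intra-cluster weight is counted over ordered
pairs. The package validates the gain against the full-formula modularity
difference on randomized graphs in its test suite, so the bookkeeping
convention cannot drift silently. Ties in $\Delta Q$ (within `1e-12`) go to
the lowest cluster index; on ties a node only moves to a strictly lower
index, which guarantees termination. If thresholding removed every edge,
all nodes become singleton clusters with a warning and $Q$ is defined as 0.

## The five objectives

For a candidate subset $GS$ the swarm minimises
$F(GS) = (f_1, f_2, f_3, f_4, f_5)$:

| objective | meaning | default evaluation |
|---|---|---|
| $f_1$ | classification error | stratified 5-fold CV, linear SVM (cost 1) |
| $f_2$ | $\sum$ edge centrality over selected pairs | redundancy penalty |
| $f_3$ | $1/\mathrm{NC}(GS)$ | representativeness reward, inverted |
| $f_4$ | $1/\mathrm{specificity}$ | false-positive penalty |
| $f_5$ | $|GS|$ | parsimony |

Cross-validation (rather than leave-one-out) keeps the inner loop linear in
the sample count; final reporting uses `loocv_accuracy()`. Folds are drawn
once per run, so fitness values are comparable and cacheable across masks.
Specificity for more than two classes is the macro-average of one-vs-rest
specificities, with a class lacking negatives contributing 1. Both
reciprocals carry an `epsilon = 1e-6` guard so fitness vectors stay finite
and dominance comparisons remain well defined. Candidates are compared by
strict Pareto dominance: $a$ dominates $b$ iff $a \le b$ everywhere and
$a < b$ somewhere.

## The swarm

Velocities follow the classical update
$v \leftarrow w v + c_1 r_1 (x_\mathrm{pbest} - x) + c_2 r_2 (x_\mathrm{gbest} - x)$,
clamped to $\pm v_\mathrm{max}$. Positions are binary, so the real velocity
must be squashed into bit decisions. Two transfer rules are implemented:

* **V-shaped (default).** Each bit *flips* with probability
  $|\tanh v|$. At $v = 0$ the position is unchanged, so once the guides
  agree a gene is off, it stays off and sparse masks persist.
* **Sigmoid.** Each bit is *resampled* to 1 with probability
  $1/(1+e^{-v})$. At $v = 0$ every bit is a fair coin. Because velocity
  decays geometrically towards 0 wherever particle and guides agree, every
  agreed-off gene regains a substantial reactivation probability within a
  few iterations. In our measurements on the synthetic benchmark this traps
  the swarm near half-density masks (about 43 of 100 genes selected,
  unchanged over 50 iterations), which defeats the parsimony objective.
  The rule is retained (`transfer = "sigmoid"`) because it is the
  historically standard choice and useful for comparison.

The package therefore defaults to the V-shaped rule: it is the established
remedy for exactly this churn pathology in binary swarm optimisation and it
is what lets the selector return subsets in the single digits to low teens,
in line with what a gene selector is for.

Initial masks select each gene independently with its normalised Fisher
score as probability, clamped to $[0.05, 0.95]$ so no gene is locked in or
out; empty masks are redrawn; velocities start at 0. Personal bests are
replaced on dominance, and on mutual nondominance with probability 0.5 — an
unbiased rule that avoids committing to any scalarisation. The global guide
is drawn per particle by a binary tournament on crowding distance from a
bounded external archive; eviction from a full archive removes the member
with the smallest crowding distance, and objective-wise extremes carry
infinite crowding distance, which both preserves front coverage and makes
the best-$f_1$ trace non-increasing by construction. The final answer is
the archive member with minimal $f_1$, ties broken by smaller $f_5$, then
smaller $f_4$, then the lexicographically smallest selected-index sequence.

### Repair

After every position update each mask is repaired: for any cluster with
fewer than $\min(\omega, |\mathrm{cluster}|)$ selected genes, the cluster's
highest-Fisher unselected gene is swapped in against the globally
lowest-Fisher selected gene whose removal leaves its own cluster covered.
If no such donor exists the gene is added without removal. Deficient
clusters are processed in ascending index, so the operator is a
deterministic function of its inputs. With the default $\omega = 1$, every
co-expression cluster keeps at least one representative in every evaluated
mask — the mechanism that spreads the subset across the whole gene space
rather than letting it collapse onto one strong cluster.

## Defaults and their reasons

| parameter | default | why |
|---|---|---|
| `top_m` | 300 | an absolute Fisher threshold is dataset-scale dependent; a top-m cut is portable |
| `theta` | 0.6 | above it, thresholding starts fragmenting real clusters and costs accuracy; below, clusters merge |
| `omega` | 1 | one representative per cluster; larger values force broader coverage |
| `swarm_size`, `max_iterations` | 30, 100 | evaluation budget; fitness caching makes repeated masks free |
| `inertia_w` | 0.7 | middle of the admissible $[0.5, 0.9]$ range |
| `c1`, `c2` | 2, 2 | classical acceleration constants |
| `v_max` | 4 | $|\tanh 4| \approx 0.999$: saturated pushes act almost surely |
| `archive_capacity` | 50 | enough to cover a 5-objective front at these problem sizes |
| `cv_folds` | 5 | the usual bias/variance compromise for $n \le 100$ |
| `classifier` | linear SVM, cost 1 | the common microarray default; `"dt"` and `"knn:k=k"` available |
| `epsilon` | 1e-6 | guards $1/\mathrm{NC}$ and $1/\mathrm{specificity}$ |

## The synthetic generator

`generate_dataset()` emulates the *shape* of small microarray studies:
few samples, many genes, planted co-expression blocks and a handful of
class-relevant genes. Genes of block $b$ share a latent factor,
$g = \sqrt\rho\, L_b + \sqrt{1-\rho}\,\varepsilon$, giving exact pairwise
population correlation $\rho$ inside the block with a closed form that
Louvain should recover. Relevant genes additionally get a class-mean shift
of $k\,\delta\,\sigma$ for the $k$-th class (0-based), which extends to any
number of classes with a single parameter; they are placed at the head of
the blocks, cycling, so that discriminative signal is spread across
clusters and the repair operator is genuinely exercised. Defaults (60
samples, 100 genes, four blocks of 20 at $\rho = 0.8$, five relevant genes
at $\delta = 2$, two balanced classes) are the scaled-down study conditions
used by the test suite and the acceptance script; the sizes keep a full
ten-seed pipeline benchmark in the low minutes on one core.

What the generator deliberately does **not** model: probe-level noise,
heteroscedasticity, batch effects, count distributions of sequencing data,
or unbalanced class designs. Tests passing on these simulations show that
the pipeline recovers planted correlation structure and planted
discriminative signal under clean Gaussian assumptions — not that it is
robust to real microarray artefacts.

One property of the generator deserves emphasis because it shapes what
"recovering the relevant genes" can mean. A relevant gene and an unshifted
gene of the same block share the latent factor, so their *difference*
cancels most of the within-class variance: a classifier given the pair
separates the classes far better than either gene alone. Subsets that pair
relevant genes with block-mates therefore reach cross-validated error
exactly 0 at these sample sizes even when one or two planted relevant
genes are missing — the planted genes are individually substitutable, and
an error-first selection rule cannot distinguish a 3-of-5 solution from a
5-of-5 solution once both measure 0. The acceptance script reports the
per-seed recovery counts so this saturation is visible rather than hidden.

## Evaluation tools

`loocv_accuracy()` is the reporting metric: $n$ single-sample folds,
accuracy as a percentage. `rank_methods()` ranks methods per dataset
(rank 1 = best, ties averaged) and averages ranks per method;
`friedman_statistic()` computes
$\chi^2 = \frac{12n}{k(k+1)} \sum_j (\bar R_j - \frac{k+1}{2})^2$ with
$k - 1$ degrees of freedom, plus an optional tie correction matching
`stats::friedman.test()`. Display values are rounded half-up to two
decimals, but full-precision values are always kept alongside, because
published tables mix rounding and truncation and a reader should be able
to tell which.

The bundled benchmark tables (`benchmark_tables()`) hold published
accuracies and gene counts of eight selection methods on seven microarray
datasets; `summarize_benchmark()` reproduces the aggregate arithmetic —
per-method means, average ranks, Friedman statistics — from them. One known
discrepancy is documented rather than reproduced: the published statistical
test reports 3 degrees of freedom for eight compared methods and a
$\chi^2$ that the printed ranks do not yield under the standard formula;
this package reports the standard statistic ($df = k-1 = 7$).

## Known limitations

* LOOCV applied to a subset selected on the same data inherits selection
  bias; honest error estimates need an untouched test split
  (`split_stratified()` exists for exactly this).
* The search is stochastic; with 30 particles and 50–100 iterations the
  archive approximates, not equals, the Pareto front. Same seed, same
  answer — but different seeds legitimately return different small subsets
  of equivalent measured quality.
* With `omega >= 1` the final subset size is bounded below by the number of
  graph clusters, including small noise communities; on data with many
  isolated genes consider raising `theta` scrutiny or setting
  `repair = FALSE` to see the unconstrained front.
* Fisher scoring is univariate: a gene relevant only through interactions
  passes the filter only if `top_m` is generous.
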