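---
title: "Methods: triad bias classification, simulation and summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triad bias classification, simulation and summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadbias)
```

## The classification model

An allohexaploid triad has one gene per subgenome (A, B, D). Given
nonnegative expression values $(a, b, d)$ for a triad in some group of
cells, the triad's composition is

$$ (f_A, f_B, f_D) = \frac{(a, b, d)}{a + b + d}, $$

a point on the 2-simplex. Classification assigns the composition to the
nearest of seven ideal centroids in plain 3-component Euclidean distance
(no 2-D projection): Balance $(1/3,1/3,1/3)$, three single-subgenome
dominance corners, and three suppressed points where one subgenome is
silent and the other two split equally. These are the unique ideal
compositions implied by the category names; `triad_centroids()` exposes
them and every classifier accepts a replacement matrix.

Assumptions worth keeping in mind:

* Classification is *purely geometric*: no statistical test, no
  maximum-distance cutoff. Every expressed triad gets a category, however
  far it sits from its winning centroid (the `distance` column lets users
  filter if they want to). This mirrors summaries that report proportions
  over exactly seven categories.
* Classification is scale-invariant within a group, so the choice of
  expression units (TPM, cp10k means, raw means) does not change a triad's
  category — but it *does* change which triads pass the expression floor
  (below).

## Tunable parameters

* `min_total_expr` (default **0.5**, units = the units of the expression
  matrix): triads with $a+b+d$ at or below this are `not_expressed`.
  Normalization is undefined at zero and near-zero totals are dominated by
  sampling noise, so a floor is unavoidable; the upstream definition of a
  per-cluster "expressed" universe is an open question in the source
  analysis, hence this is a flag rather than a constant. Because the floor
  is applied to mean expression, the pseudobulk mode matters: cp10k and
  raw means filter different triads even though classification itself is
  scale-invariant. The mode in use is recorded in the run manifest.
* `normalization` (default **cp10k**): each cell scaled to 10,000 total
  counts before group averaging, the convention of standard single-cell
  average-expression functions; `raw_mean` is exact for the pooling
  identity (pooled pseudobulk = cell-count-weighted mean of cluster
  pseudobulks) and is used by the consistency tests.
* Tie-breaking: a composition exactly equidistant from two centroids is a
  measure-zero event but reachable (e.g. the midpoint of Balance and
  D.suppressed, $(5/12, 5/12, 1/6)$). Ties resolve to Balance first — bias
  toward the null category — then A/B/D dominant, then A/B/D suppressed.
  Floating point cannot represent such ties exactly, so "tie" means
  squared distances within $10^{-12}$.

## The synthetic generator: what it emulates

`sim_config()` / `plant_truth()` / `simulate_counts()` generate a
gene-by-cell count matrix with known per-cluster triad bias:

1. per cluster and triad, a category from the cluster's mixture over the
   seven categories;
2. a latent composition $\theta \sim
   \mathrm{Dirichlet}(\kappa\,c + \varepsilon)$ around the category
   centroid $c$ ($\varepsilon = 10^{-3}$ keeps zero coordinates
   sampleable; $\kappa$ = 200 by default). The floor could equally have
   been placed inside the product, $\kappa(c + \varepsilon)$, but that
   form leaves a $\sim 2\varepsilon$ bias at any concentration; the
   additive form above is the one whose $\kappa \to \infty$ limit
   converges exactly to the centroids;
3. per-cell triad totals $\mathrm{NB}(\mu_t, \text{size}=2)$ with
   $\mu_t \sim \Gamma(\text{shape}=2, \text{mean}=20)$ across triads,
   split across A/B/D by a multinomial at $\theta$, then independent
   Bernoulli dropout (rate 0.3).

Defaults are the stated world: 20 clusters, 2,000 triads, 150 cells per
cluster, a 55% Balance mixture with suppressed categories twice as likely
as dominant ones — emulating a root single-nucleus atlas in which roughly
40–45% of triads are biased and suppression outweighs dominance. They were
chosen once, for realism, and are not tuned to test outcomes.

The trajectory variant plants an *asymmetry gradient*: segment 1 draws
categories at the first target unbalanced fraction; each later segment
inherits the previous segment's categories and flips just enough
Balance triads to non-Balance (or back) to hit its target, so consecutive
segments share most of their planted structure, as real differentiation
would.

What the generator does **not** emulate: gene-length/GC effects, ambient
RNA, doublets, cluster-correlated library sizes, or any within-cluster
composition heterogeneity (all cells of a cluster share one latent
composition per triad). A green recovery test therefore establishes that
the pipeline inverts *this* noise model at realistic sparsity — not that
it is robust to artifacts the model lacks.

## Bulk versus cluster: why pooling hides bias

Pooled (bulk-like) expression is the cell-weighted mean of cluster
signals. Opposing biases cancel: a triad A.dominant $(1,0,0)$ in one
cluster and A.suppressed $(0,\frac12,\frac12)$ in an equal-sized other
pools to $(\frac12,\frac14,\frac14)$, which is nearest Balance (distance
0.204 versus 0.354 to the suppressed centroids). `balanced_breakdown()`
quantifies this: among triads called Balance in bulk, the distribution of
their per-cluster categories. The denominator for the published-style
percentages is ambiguous (all bulk-balanced triads versus those also
expressed in the cluster), so both are emitted
(`unbalanced_fraction`, `unbalanced_fraction_all`).

## Specificity and cross-species comparison

The Shannon-entropy specificity index of a gene's per-cluster profile $p$
is $S = 1 - H(p)/\log_2 n$, normalized to $[0,1]$ (0 = uniform, 1 =
single-cluster). The index's normalization is not fixed by its name alone;
the normalized form is the package default and the unnormalized
$\log_2 n - H$ is available via `normalized = FALSE`.

Cross-species cluster matching correlates ortholog-collapsed per-cluster
means (Spearman, two-sided asymptotic $p$, Benjamini–Hochberg across all
cluster pairs, $\alpha = 0.05$). The upstream significance procedure was
unstated; the asymptotic-test-plus-BH choice is standard and reproducible.
Ortholog policy defaults to `one_to_one` to avoid double-counting in both
the correlation and the overlapped-marker counts; `mean` keeps
many-to-many pairs.

## Numerical and reproducibility choices

* All randomness flows from one master seed; each simulation stage derives
  child seeds deterministically (`seed + 1000003 * salt`, then
  `sample.int`), so stages are individually reproducible and inserting a
  stage does not shift later ones.
* On-disk matrices are MatrixMarket coordinate, integer, 1-based,
  gzip-compressed with features/barcodes TSVs; the reader refuses
  non-coordinate dialects and accepts the legacy 2-column `genes.tsv`.
  R's gzip output carries no timestamp, so identical runs are
  byte-identical — the determinism contract is tested at the byte level.
* Degenerate inputs: zero-total triads are an error in `normalize_triads`
  but a `not_expressed` label in the matrix classifiers; zero-count cells
  survive cp10k scaling as all-zero with a warning; a zero dominant count
  makes the suppressed/dominant ratio `Inf` with a warning (small clusters
  legitimately lack dominant calls); constant profiles yield NA
  correlations, logged.

## Known limitations

* The classifier inherits the coarseness of seven ideal categories:
  compositions near simplex edges between centroids are assigned, not
  flagged, and no uncertainty accompanies a call.
* `min_total_expr` interacts with normalization mode; comparisons across
  datasets should fix both.
* Trajectory analysis consumes pseudotime/segment annotations; it does not
  infer trajectories, and segment granularity is the user's choice
  (labels or equal-count bins).
* Accession-scale headline percentages from real wheat root data are not
  reproducible from this package alone; the test suite validates the
  machinery on synthetic data with planted truth instead.
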