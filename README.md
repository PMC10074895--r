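# triadbias

Quantify asymmetric homoeolog expression in allohexaploid wheat — at bulk
and single-cell resolution.

## The problem

Hexaploid bread wheat (*Triticum aestivum*, AABBDD) carries most genes as
**triads**: three homoeologous copies, one per subgenome. The three copies
are often *not* expressed equally — one subgenome's copy can dominate or be
suppressed — and bulk RNA-seq averages this asymmetry over many cell types,
hiding the fact that a triad balanced "on average" may be strongly biased
within individual cell clusters, with the bias even shifting along
differentiation trajectories. `triadbias` provides the analysis layer for
this question: it takes a triad table, an expression matrix (10x-style
single-cell counts or bulk TSV) and a cell annotation, and produces bias
calls, per-cluster summaries, bulk-versus-cluster breakdowns and
trajectory-resolved asymmetry profiles. A built-in synthetic generator
with planted ground truth replaces restricted raw data for validation.

## The model

For a triad with expression (a, b, d) (A, B, D subgenome copies), the
normalized composition is the point on the 2-simplex

    (f_A, f_B, f_D) = (a, b, d) / (a + b + d),   f_A + f_B + f_D = 1.

Each expressed triad is assigned to the bias category whose **ideal
centroid** is nearest in Euclidean distance:

| category     | centroid (f_A, f_B, f_D) |
|--------------|--------------------------|
| Balance      | (1/3, 1/3, 1/3)          |
| A.dominant   | (1, 0, 0)                |
| B.dominant   | (0, 1, 0)                |
| D.dominant   | (0, 0, 1)                |
| A.suppressed | (0, 1/2, 1/2)            |
| B.suppressed | (1/2, 0, 1/2)            |
| D.suppressed | (1/2, 1/2, 0)            |

Triads with total expression ≤ `min_total_expr` (default 0.5) are reported
as `not_expressed`. Cluster-level expression is the pseudobulk mean of the
cluster's cells (each cell scaled to 10,000 counts by default). The package
also computes the Shannon-entropy specificity index
S = 1 − H(p)/log2(n) for cluster-specific gene detection, and cross-species
cluster correlation (Spearman ρ with BH correction) over ortholog-mapped
marker genes.

## Worked example

Simulate a small atlas with planted bias, classify, and summarize:

```r
library(triadbias)
cfg   <- sim_config(n_triads = 1000, n_clusters = 4,
                    cells_per_cluster = 150, seed = 1)
truth <- plant_truth(cfg)
sim   <- simulate_counts(truth, cfg)
pb    <- pseudobulk_means(sim$counts, sim$annotation)   # cp10k means
calls <- classify_groups(pb, sim$triads, min_total_expr = 0.5)
head(category_proportions(calls), 8)
```

```
      group      category count proportion
1 cluster01       Balance   552     0.5553
2 cluster01    A.dominant    50     0.0503
3 cluster01    B.dominant    44     0.0443
4 cluster01    D.dominant    41     0.0412
5 cluster01  A.suppressed   108     0.1087
6 cluster01  B.suppressed   105     0.1056
7 cluster01  D.suppressed    94     0.0946
8 cluster01 not_expressed     6         NA
```

The defaults plant 55% Balance with suppression twice as likely as
dominance, and the pipeline recovers that mixture: ~55% of expressed
triads are Balance and each subgenome's suppressed/dominant ratio is ~2:

```r
summary <- category_proportions(calls)
suppressed_dominant_table(summary)[1:3, ]
```
```
      group subgenome n_suppressed n_dominant ratio
1 cluster01         A          108         50  2.16
2 cluster01         B          105         44  2.39
3 cluster01         D           94         41  2.29
```

How many triads that look balanced in the pooled ("bulk") signal are biased
within each cluster:

```r
pooled <- data.frame(cell_id = sim$annotation$cell_id, cluster = "bulk")
bulk   <- classify_matrix(pseudobulk_means(sim$counts, pooled),
                          sim$triads, "bulk")
balanced_breakdown(bulk, calls)$unbalanced
```
```
      group n_bulk_balanced n_expressed unbalanced_fraction
1 cluster01             827         826               0.402
2 cluster02             827         825               0.392
3 cluster03             827         827               0.405
4 cluster04             827         826               0.396
```

Here ~40% of bulk-balanced triads are called non-Balance per cluster —
because cluster-level compositions are independent draws, whereas the
pooled mean shrinks toward Balance. `asymmetry_along_trajectory()` produces
the analogous unbalanced-fraction profile over pseudotime segments.

## Command line

```sh
Rscript -e 'triadbias::tb_cli()' simulate --out sim_out --seed 1
Rscript -e 'triadbias::tb_cli()' classify \
    --matrix sim_out/matrix --annotation sim_out/annotation.tsv \
    --triads sim_out/triads.tsv --min-total-expr 0.5 --out results
```

Subcommands: `simulate`, `classify`, `trajectory`, `specificity`,
`crosscorr`, `run-all`. Outputs are plain TSV/CSV plus a JSON run manifest.

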