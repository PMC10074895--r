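# Shared fixtures and independent oracles.

# Write a complete n-triad TSV; returns path.
write_triad_tsv <- function(n, path = tempfile(fileext = ".tsv"),
                            prefix = "Tr") {
  df <- data.frame(triad_id = sprintf("%s%05d", prefix, seq_len(n)),
                   A = sprintf("%s%05d-A", prefix, seq_len(n)),
                   B = sprintf("%s%05d-B", prefix, seq_len(n)),
                   D = sprintf("%s%05d-D", prefix, seq_len(n)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tiny_triads <- function(n = 3) {
  triad_table(data.frame(
    triad_id = sprintf("t%02d", seq_len(n)),
    gene_a = sprintf("gA%02d", seq_len(n)),
    gene_b = sprintf("gB%02d", seq_len(n)),
    gene_d = sprintf("gD%02d", seq_len(n)),
    stringsAsFactors = FALSE))
}

# Independent brute-force nearest-centroid classifier: explicit per-point
# loop over all centroids, plain arithmetic, first index wins ties.
oracle_classify <- function(comp, centroids = triad_centroids()) {
  comp <- rbind(comp)
  out_cat <- character(nrow(comp)); out_d <- numeric(nrow(comp))
  for (i in seq_len(nrow(comp))) {
    ds <- numeric(nrow(centroids))
    for (k in seq_len(nrow(centroids)))
      ds[k] <- sqrt(sum((comp[i, ] - centroids[k, ])^2))
    best <- which(ds <= min(ds) + 1e-9)[1]
    out_cat[i] <- rownames(centroids)[best]
    out_d[i] <- ds[best]
  }
  data.frame(category = out_cat, distance = out_d,
             stringsAsFactors = FALSE)
}

# Uniform points on the 2-simplex (Dirichlet(1,1,1)).
runif_simplex <- function(n) {
  g <- matrix(-log(runif(3 * n)), ncol = 3)
  g / rowSums(g)
}

# Small deterministic simulation shared across tests.
small_sim <- function(seed = 42, ...) {
  cfg <- sim_config(n_triads = 150, n_clusters = 3, cells_per_cluster = 60,
                    seed = seed, ...)
  truth <- plant_truth(cfg)
  c(list(config = cfg, truth = truth), simulate_counts(truth, cfg))
}
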