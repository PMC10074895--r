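test_that("pseudobulk_means: arithmetic, identity, and cp10k oracle", {
  m <- Matrix::Matrix(matrix(c(2, 0, 4, 6), nrow = 1,
                             dimnames = list("g1", paste0("c", 1:4))),
                      sparse = TRUE)
  ann <- data.frame(cell_id = paste0("c", 1:4),
                    cluster = c("x", "x", "y", "y"))
  pb <- pseudobulk_means(m, ann, normalization = "raw_mean")
  expect_equal(unname(pb[1, ]), c(1, 5))
  expect_equal(colnames(pb), c("x", "y"))  # first-appearance order

  # one cell per group: pseudobulk equals the (normalized) cell
  m2 <- Matrix::Matrix(matrix(c(3, 7, 1, 9), nrow = 2,
                              dimnames = list(c("g1", "g2"),
                                              c("c1", "c2"))), sparse = TRUE)
  ann2 <- data.frame(cell_id = c("c1", "c2"), cluster = c("a", "b"))
  pbr <- pseudobulk_means(m2, ann2, normalization = "raw_mean")
  expect_equal(unname(pbr), unname(as.matrix(m2)))
  pbc <- pseudobulk_means(m2, ann2, normalization = "cp10k")
  expect_equal(unname(Matrix::colSums(pbc)), c(1e4, 1e4))

  # cp10k equals a brute-force per-gene mean of scaled cells
  sim <- small_sim()
  pb3 <- pseudobulk_means(sim$counts, sim$annotation)
  dense <- as.matrix(sim$counts)
  scaled <- sweep(dense, 2, pmax(colSums(dense), 1e-300), "/") * 1e4
  for (g in unique(sim$annotation$cluster)) {
    cells <- sim$annotation$cell_id[sim$annotation$cluster == g]
    expect_equal(pb3[, g], rowMeans(scaled[, cells, drop = FALSE]),
                 tolerance = 1e-10)
  }

  expect_error(pseudobulk_means(m2, ann2[1, , drop = FALSE]),
               "missing from annotation")
})

test_that("classify_groups matches the per-triad oracle and handles zero groups", {
  sim <- small_sim()
  pb <- pseudobulk_means(sim$counts, sim$annotation)
  calls <- classify_groups(pb, sim$triads, min_total_expr = 0.5)
  expect_named(calls, colnames(pb))
  g <- colnames(pb)[2]
  a <- pb[sim$triads$gene_a, g]; b <- pb[sim$triads$gene_b, g]
  d <- pb[sim$triads$gene_d, g]
  expr <- (a + b + d) > 0.5
  orc <- oracle_classify((cbind(a, b, d) / (a + b + d))[expr, ])
  expect_equal(as.character(calls[[g]]$category[expr]), orc$category)
  expect_true(all(calls[[g]]$category[!expr] == "not_expressed"))

  # all-zero group: everything not_expressed
  tt <- tiny_triads(2)
  z <- matrix(0, 6, 1, dimnames = list(c(tt$gene_a, tt$gene_b, tt$gene_d),
                                       "dead"))
  expect_true(all(classify_groups(z, tt)$dead$category == "not_expressed"))
})

test_that("balanced_breakdown counts bulk-balanced fates with both denominators", {
  tt <- tiny_triads(5)
  mk_calls <- function(cats, group) {
    data.frame(triad_id = tt$triad_id, group = group,
               fa = ifelse(cats == "not_expressed", NA, 1/3),
               fb = 1/3, fd = 1/3,
               category = factor(cats, levels = c(
                 "Balance", "A.dominant", "B.dominant", "D.dominant",
                 "A.suppressed", "B.suppressed", "D.suppressed",
                 "not_expressed")),
               distance = 0, stringsAsFactors = FALSE)
  }
  bulk <- mk_calls(c("Balance", "Balance", "Balance", "Balance",
                     "A.dominant"), "bulk")
  cl <- list(
    c1 = mk_calls(c("Balance", "Balance", "A.dominant", "D.suppressed",
                    "Balance"), "c1"),
    c2 = mk_calls(c("Balance", "not_expressed", "A.dominant", "Balance",
                    "Balance"), "c2"))
  bd <- balanced_breakdown(bulk, cl)
  # 4 bulk-balanced; c1: {Bal, Bal, A.dom, D.sup} -> unbalanced 0.5
  expect_equal(bd$unbalanced$unbalanced_fraction[1], 0.5)
  expect_equal(bd$unbalanced$n_bulk_balanced, c(4, 4))
  # c2: one not_expressed -> denominator 3, one A.dominant
  expect_equal(bd$unbalanced$n_expressed[2], 3)
  expect_equal(bd$unbalanced$unbalanced_fraction[2], 1/3)
  expect_equal(bd$unbalanced$unbalanced_fraction_all[2], 1/4)
  # clusters identical to bulk: unbalanced fraction 0
  bd0 <- balanced_breakdown(bulk, list(same = bulk))
  expect_equal(bd0$unbalanced$unbalanced_fraction, 0)
  # disjoint triad sets rejected
  other <- mk_calls(rep("Balance", 5), "o")
  other$triad_id <- paste0("x", other$triad_id)
  expect_error(balanced_breakdown(bulk, list(o = other)), "different triad")
})

test_that("category_proportions: counting, degenerate group, denominator discipline", {
  tt <- tiny_triads(10)
  cats <- c(rep("Balance", 6), rep("A.dominant", 2), rep("A.suppressed", 2))
  calls <- list(g1 = data.frame(
    triad_id = tt$triad_id, group = "g1", fa = 1/3, fb = 1/3, fd = 1/3,
    category = cats, distance = 0, stringsAsFactors = FALSE))
  s <- category_proportions(calls)
  expect_equal(s$proportion[s$category == "Balance"], 0.6)
  expect_equal(s$proportion[s$category == "A.dominant"], 0.2)
  expect_equal(sum(s$proportion[s$category %in% s$category[1:7]]), 1)

  # empty expressed set: NA proportions, zero counts
  calls0 <- list(g0 = data.frame(
    triad_id = tt$triad_id, group = "g0", fa = NA, fb = NA, fd = NA,
    category = "not_expressed", distance = NA, stringsAsFactors = FALSE))
  s0 <- category_proportions(calls0)
  expect_true(all(is.na(s0$proportion)))
  expect_equal(s0$count[s0$category == "not_expressed"], 10)

  # audit: counts + not_expressed = triad-table size, per group, on real sim
  sim <- small_sim()
  pb <- pseudobulk_means(sim$counts, sim$annotation)
  cl <- classify_groups(pb, sim$triads, min_total_expr = 0.5)
  ss <- category_proportions(cl)
  tot <- tapply(ss$count, ss$group, sum)
  expect_true(all(tot == nrow(sim$triads)))
})

test_that("suppressed_dominant_ratio arithmetic, Inf sentinel, planted 2:1", {
  tt <- tiny_triads(28)
  cats <- c(rep("A.suppressed", 18), rep("A.dominant", 10))
  calls <- list(g = data.frame(triad_id = tt$triad_id, group = "g",
                               fa = 1/3, fb = 1/3, fd = 1/3,
                               category = cats, distance = 0,
                               stringsAsFactors = FALSE))
  s <- category_proportions(calls)
  expect_equal(suppressed_dominant_ratio(s, "A", "g"), 1.8)
  expect_warning(r <- suppressed_dominant_ratio(s, "B", "g"), "Inf")
  expect_identical(r, Inf)

  # planted 2:1 suppressed:dominant recovers ratio ~2 at 3000 triads
  probs <- c(0.40, 0.10, 0.10, 0.10, 0.10, 0.10, 0.10)
  # A.suppressed twice A.dominant:
  probs <- c(0.40, 0.07, 0.10, 0.10, 0.14, 0.10, 0.09)
  cfg <- sim_config(n_triads = 3000, n_clusters = 1,
                    cells_per_cluster = 150, category_probs = probs,
                    seed = 12)
  sim <- simulate_counts(plant_truth(cfg), cfg)
  pb <- pseudobulk_means(sim$counts, sim$annotation)
  ss <- category_proportions(classify_groups(pb, sim$triads))
  ratio <- suppressed_dominant_ratio(ss, "A", "cluster01")
  # sampling sd of the count ratio at these expected counts (420/210) is
  # ~0.17, so a 3-sigma band is 2 +/- 0.5
  expect_gt(ratio, 1.5); expect_lt(ratio, 2.5)

  tab <- suppressed_dominant_table(ss)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$ratio[tab$subgenome == "A"], ratio)
})

test_that("marker_bias_summary maps markers to triads and counts bias", {
  tt <- tiny_triads(4)
  calls <- list(g = data.frame(
    triad_id = tt$triad_id, group = "g", fa = 1/3, fb = 1/3, fd = 1/3,
    category = c("Balance", "A.dominant", "Balance", "not_expressed"),
    distance = 0, stringsAsFactors = FALSE))
  # markers hit triads 1 (via A gene) and 2 (via D gene); one unknown gene
  mk <- list(g = c("gA01", "gD02", "unknown_gene"))
  s <- marker_bias_summary(calls, mk, tt)
  expect_equal(s$n_markers_in_triads, 2)
  expect_equal(s$n_marker_triads, 2)
  expect_equal(s$fraction_unbalanced, 0.5)

  # markers hitting only Balance triads -> 0; empty set -> NA
  s0 <- marker_bias_summary(calls, list(g = c("gB01", "gA03")), tt)
  expect_equal(s0$fraction_unbalanced, 0)
  sNA <- marker_bias_summary(calls, list(g = character(0)), tt)
  expect_true(is.na(sNA$fraction_unbalanced))

  # marker triads planted non-Balance with prob 0.6 recover ~0.6 at n=500
  cfg <- sim_config(n_triads = 500, n_clusters = 1, cells_per_cluster = 150,
                    category_probs = c(0.4, rep(0.6 / 6, 6)), seed = 21)
  sim <- simulate_counts(plant_truth(cfg), cfg)
  pb <- pseudobulk_means(sim$counts, sim$annotation)
  cl <- classify_groups(pb, sim$triads)
  mk_all <- list(cluster01 = sim$triads$gene_b)  # every triad is a marker triad
  sm <- marker_bias_summary(cl, mk_all, sim$triads)
  expect_equal(sm$fraction_unbalanced, 0.6, tolerance = 0.1)
})

test_that("pooling consistency: bulk pseudobulk equals weighted cluster mean", {
  sim <- small_sim()
  pb_cl <- pseudobulk_means(sim$counts, sim$annotation,
                            normalization = "raw_mean")
  pooled <- data.frame(cell_id = sim$annotation$cell_id, cluster = "all")
  pb_all <- pseudobulk_means(sim$counts, pooled, normalization = "raw_mean")
  sizes <- table(sim$annotation$cluster)[colnames(pb_cl)]
  weighted <- pb_cl %*% (as.numeric(sizes) / sum(sizes))
  expect_equal(unname(pb_all[, 1]), unname(weighted[, 1]), tolerance = 1e-12)
  # hence identical bias calls
  c1 <- classify_matrix(pb_all, sim$triads, "all")
  c2 <- classify_matrix(cbind(all = weighted[, 1]), sim$triads, "all")
  expect_equal(as.character(c1$category), as.character(c2$category))
})
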