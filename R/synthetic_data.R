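# Synthetic allohexaploid single-cell data with planted triad bias.
#
# Generative model (per cluster c, triad t, cell j):
#   category[c,t]   ~ Categorical(category_probs[c, ])
#   theta[c,t]      ~ Dirichlet(kappa * centroid(category) + eps)     latent composition
#   mu_t            ~ Gamma(shape, scale)                             triad mean total
#   total[t,j]      ~ NegBinom(mu = mu_t, size = nb_dispersion)
#   (a,b,d)[t,j]    ~ Multinomial(total[t,j], theta[c,t])
#   each gene count zeroed independently with prob dropout_rate
# All stages are seeded from a single master seed via derived child seeds.

#' Simulation configuration for the synthetic allopolyploid generator
#'
#' Bundles and validates every knob of the generative model. Defaults
#' emulate the statistical structure of a wheat root single-nucleus atlas:
#' many clusters, thousands of triads, a cluster-specific mixture over the
#' seven bias categories, overdispersed counts and heavy dropout.
#'
#' @param n_triads Number of homoeolog triads (3 genes each).
#' @param n_clusters Number of cell clusters.
#' @param cells_per_cluster Cells per cluster (scalar or per-cluster vector).
#' @param category_probs Either a length-7 probability vector (recycled to
#'   every cluster) or an \code{n_clusters} x 7 matrix, columns in the order
#'   of [triad_centroids()] rows. Rows must sum to 1. Default plants 55\%
#'   Balance with the remainder spread over the six biased categories,
#'   suppressed categories twice as likely as dominant ones — matching the
#'   bulk-level picture of roughly 40--45\% biased triads with suppression
#'   outweighing dominance.
#' @param dirichlet_concentration Noise scale kappa > 0; latent compositions
#'   are drawn from Dirichlet(kappa * centroid + eps). Higher = tighter.
#' @param mean_total_expr Expected triad-level total expression; per-triad
#'   means are Gamma(\code{gamma_shape}, scale = mean_total_expr/gamma_shape).
#' @param gamma_shape Shape of the across-triad mean distribution.
#' @param nb_dispersion Negative-binomial size parameter for per-cell triad
#'   totals (smaller = more overdispersed).
#' @param dropout_rate Probability in [0,1] that any single gene count in a
#'   cell is zeroed.
#' @param trajectory Optional list describing a branching trajectory:
#'   \code{segments} (ordered labels), optional \code{branch} (parallel
#'   branch label per segment, default one branch), \code{targets}
#'   (per-segment planted unbalanced fraction in [0,1]),
#'   \code{cells_per_segment}.
#' @param eps Floor added to the Dirichlet parameters kappa * centroid
#'   (Dirichlet is undefined at zero parameters).
#' @param seed Master integer seed; all stages derive child seeds from it.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_triads = 2000,
                       n_clusters = 20,
                       cells_per_cluster = 150,
                       category_probs = NULL,
                       dirichlet_concentration = 200,
                       mean_total_expr = 20,
                       gamma_shape = 2,
                       nb_dispersion = 2,
                       dropout_rate = 0.3,
                       trajectory = NULL,
                       eps = 1e-3,
                       seed = 1L) {
  if (is.null(category_probs))
    category_probs <- c(0.55, rep(0.05, 3), rep(0.10, 3))
  if (is.null(dim(category_probs)))
    category_probs <- matrix(category_probs, nrow = n_clusters, ncol = 7,
                             byrow = TRUE)
  category_probs <- as.matrix(category_probs)
  colnames(category_probs) <- TRIAD_CATEGORIES
  stopifnot(n_triads >= 1, n_clusters >= 1,
            nrow(category_probs) == n_clusters, ncol(category_probs) == 7)
  if (any(category_probs < 0) ||
      any(abs(rowSums(category_probs) - 1) > 1e-8))
    stop("category_probs rows must be nonnegative and sum to 1")
  if (dirichlet_concentration <= 0)
    stop("dirichlet_concentration must be > 0")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("dropout_rate must be in [0, 1]")
  cells_per_cluster <- rep_len(as.integer(cells_per_cluster), n_clusters)
  if (any(cells_per_cluster < 1)) stop("cells_per_cluster must be positive")
  if (!is.null(trajectory)) {
    if (is.null(trajectory$segments)) stop("trajectory$segments is required")
    k <- length(trajectory$segments)
    if (is.null(trajectory$branch))
      trajectory$branch <- rep("branch1", k)
    if (is.null(trajectory$targets))
      stop("trajectory$targets (per-segment unbalanced fractions) is required")
    if (length(trajectory$targets) != k || length(trajectory$branch) != k)
      stop("trajectory fields must have one entry per segment")
    if (any(trajectory$targets < 0 | trajectory$targets > 1))
      stop("trajectory targets must be fractions in [0, 1]")
    if (is.null(trajectory$cells_per_segment))
      trajectory$cells_per_segment <- 200L
    trajectory$cells_per_segment <-
      rep_len(as.integer(trajectory$cells_per_segment), k)
  }
  structure(list(n_triads = as.integer(n_triads),
                 n_clusters = as.integer(n_clusters),
                 cells_per_cluster = cells_per_cluster,
                 category_probs = category_probs,
                 dirichlet_concentration = dirichlet_concentration,
                 mean_total_expr = mean_total_expr,
                 gamma_shape = gamma_shape,
                 nb_dispersion = nb_dispersion,
                 dropout_rate = dropout_rate,
                 trajectory = trajectory,
                 eps = eps,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic child seeds from the master seed; RNG state is restored.
derive_seeds <- function(seed, n, salt = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + 1000003L * salt) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) { g[which.max(alpha)] <- 1 }  # numeric underflow guard
  g / sum(g)
}

#' Plant per-cluster triad bias truth
#'
#' For every cluster x triad pair, draws a bias category from the cluster's
#' category mixture and a latent simplex composition from a Dirichlet
#' centred on that category's ideal centroid. This is the ground truth that
#' [simulate_counts()] realizes as noisy counts and that recovery tests
#' compare against.
#'
#' @param config A [sim_config()].
#' @return A data.frame of class \code{truth_table}: one row per
#'   cluster x triad with columns \code{cluster}, \code{triad_id},
#'   \code{category}, \code{fa}, \code{fb}, \code{fd}.
#' @export
plant_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 1L, salt = 1L)
  set.seed(seeds[1])
  kappa <- config$dirichlet_concentration
  cents <- triad_centroids()
  triad_ids <- sprintf("triad%05d", seq_len(config$n_triads))
  rows <- vector("list", config$n_clusters)
  for (c in seq_len(config$n_clusters)) {
    cat_idx <- sample.int(7L, config$n_triads, replace = TRUE,
                          prob = config$category_probs[c, ])
    comp <- t(vapply(cat_idx, function(k)
      rdirichlet1(kappa * cents[k, ] + config$eps),
      numeric(3)))
    rows[[c]] <- data.frame(cluster = sprintf("cluster%02d", c),
                            triad_id = triad_ids,
                            category = TRIAD_CATEGORIES[cat_idx],
                            fa = comp[, 1], fb = comp[, 2], fd = comp[, 3],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("truth_table", "data.frame")
  out
}

# Gene names for triad i: <triad_id>-A/-B/-D. Returns the matching
# triad_table.
truth_triad_table <- function(triad_ids) {
  triad_table(data.frame(triad_id = triad_ids,
                         gene_a = paste0(triad_ids, "-A"),
                         gene_b = paste0(triad_ids, "-B"),
                         gene_d = paste0(triad_ids, "-D"),
                         stringsAsFactors = FALSE))
}

# Vectorized multinomial split of totals N into (a, b, d) with per-entry
# probability rows p (n x 3): a ~ Binom(N, p1), b ~ Binom(N - a, p2/(p2+p3)).
split_abd <- function(N, p) {
  a <- stats::rbinom(length(N), N, p[, 1])
  rest <- N - a
  pb <- ifelse(p[, 2] + p[, 3] > 0, p[, 2] / (p[, 2] + p[, 3]), 0)
  b <- stats::rbinom(length(N), rest, pb)
  cbind(a = a, b = b, d = rest - b)
}

#' Simulate a gene-by-cell count matrix from planted truth
#'
#' Realizes the planted compositions as sparse single-cell counts: per cell
#' and triad a negative-binomial total (triad means Gamma-distributed across
#' triads), split across the A/B/D homoeologs by a multinomial draw at the
#' cluster's latent composition, then independent Bernoulli dropout per gene
#' count.
#'
#' @param truth Output of [plant_truth()] (or of the trajectory variant).
#' @param config The [sim_config()] used to create \code{truth}.
#' @param cells_per_group Optional per-group cell counts overriding
#'   \code{config$cells_per_cluster} (used by the trajectory simulator).
#' @return A list: \code{counts} (sparse dgCMatrix, genes x cells),
#'   \code{annotation} (data.frame cell_id, cluster), \code{triads}
#'   (a [triad_table()]).
#' @export
simulate_counts <- function(truth, config, cells_per_group = NULL) {
  stopifnot(inherits(config, "sim_config"))
  groups <- unique(truth$cluster)
  triad_ids <- unique(truth$triad_id)
  n_t <- length(triad_ids)
  if (nrow(truth) != n_t * length(groups))
    stop("truth table is not one record per cluster x triad")
  if (is.null(cells_per_group))
    cells_per_group <- rep_len(config$cells_per_cluster, length(groups))
  seeds <- derive_seeds(config$seed, 2L + length(groups), salt = 2L)
  set.seed(seeds[1])
  mu_t <- stats::rgamma(n_t, shape = config$gamma_shape,
                        scale = config$mean_total_expr / config$gamma_shape)
  genes <- as.vector(rbind(paste0(triad_ids, "-A"),
                           paste0(triad_ids, "-B"),
                           paste0(triad_ids, "-D")))
  blocks <- vector("list", length(groups))
  ann <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    set.seed(seeds[2L + gi])
    g <- groups[gi]
    m <- cells_per_group[gi]
    th <- truth[truth$cluster == g, ]
    th <- th[match(triad_ids, th$triad_id), ]
    p <- as.matrix(th[, c("fa", "fb", "fd")])
    # totals: n_t x m, triad means recycled down columns
    N <- stats::rnbinom(n_t * m, mu = rep(mu_t, m), size = config$nb_dispersion)
    abd <- split_abd(N, p[rep(seq_len(n_t), m), ])
    # interleave rows as A,B,D per triad -> (3 n_t) x m dense block
    block <- matrix(0L, nrow = 3L * n_t, ncol = m)
    idx <- rep(seq_len(n_t), m)
    col <- rep(seq_len(m), each = n_t)
    block[cbind(3L * idx - 2L, col)] <- abd[, "a"]
    block[cbind(3L * idx - 1L, col)] <- abd[, "b"]
    block[cbind(3L * idx,      col)] <- abd[, "d"]
    if (config$dropout_rate > 0)
      block <- block * matrix(stats::rbinom(length(block), 1L,
                                            1 - config$dropout_rate),
                              nrow = nrow(block))
    blocks[[gi]] <- methods::as(Matrix::Matrix(block, sparse = TRUE),
                                "CsparseMatrix")
    ann[[gi]] <- data.frame(cell_id = sprintf("%s_cell%04d", g, seq_len(m)),
                            cluster = g, stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, blocks)
  annotation <- do.call(rbind, ann)
  rownames(counts) <- genes
  colnames(counts) <- annotation$cell_id
  list(counts = counts, annotation = annotation,
       triads = truth_triad_table(triad_ids))
}

#' Plant and annotate a branching pseudotime trajectory
#'
#' Builds a segment-level truth table whose planted unbalanced fraction
#' follows the configured per-segment targets, plus a cell annotation with
#' pseudotime, branch and segment labels. Later segments inherit the
#' previous segment's categories and reassign just enough Balance triads to
#' non-Balance categories (or back) to hit each target, so the asymmetry
#' gradient is a gradual reshuffling, not an independent redraw.
#' Non-monotone target sequences are allowed but logged.
#'
#' @param config A [sim_config()] with \code{trajectory} set.
#' @return A list: \code{truth} (truth_table with one record per
#'   segment x triad; \code{cluster} holds the segment label),
#'   \code{annotation} (cell_id, cluster = segment, segment, branch,
#'   pseudotime in [0,1], segment_order).
#' @export
simulate_trajectory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  traj <- config$trajectory
  if (is.null(traj)) stop("config$trajectory is not set")
  segs <- traj$segments
  k <- length(segs)
  if (any(diff(traj$targets) < 0))
    message("trajectory targets are non-monotone; planting as given")
  seeds <- derive_seeds(config$seed, k + 1L, salt = 3L)
  kappa <- config$dirichlet_concentration
  cents <- triad_centroids()
  triad_ids <- sprintf("triad%05d", seq_len(config$n_triads))
  n_t <- config$n_triads

  draw_comp <- function(cat_idx)
    t(vapply(cat_idx, function(kk)
      rdirichlet1(kappa * cents[kk, ] + config$eps), numeric(3)))

  set.seed(seeds[1])
  # segment 1: exact planted count of unbalanced triads (rounded target)
  n_unb <- round(traj$targets[1] * n_t)
  cat_idx <- rep(1L, n_t)
  unb <- sample.int(n_t, n_unb)
  cat_idx[unb] <- sample(2:7, n_unb, replace = TRUE)
  rows <- vector("list", k)
  comp <- draw_comp(cat_idx)
  rows[[1]] <- data.frame(cluster = segs[1], triad_id = triad_ids,
                          category = TRIAD_CATEGORIES[cat_idx],
                          fa = comp[, 1], fb = comp[, 2], fd = comp[, 3],
                          stringsAsFactors = FALSE)
  for (s in seq_len(k)[-1]) {
    set.seed(seeds[s])
    want <- round(traj$targets[s] * n_t)
    have <- sum(cat_idx != 1L)
    if (want > have) {
      bal <- which(cat_idx == 1L)
      flip <- sample(bal, min(want - have, length(bal)))
      cat_idx[flip] <- sample(2:7, length(flip), replace = TRUE)
    } else if (want < have) {
      nb <- which(cat_idx != 1L)
      flip <- sample(nb, min(have - want, length(nb)))
      cat_idx[flip] <- 1L
    }
    comp <- draw_comp(cat_idx)
    rows[[s]] <- data.frame(cluster = segs[s], triad_id = triad_ids,
                            category = TRIAD_CATEGORIES[cat_idx],
                            fa = comp[, 1], fb = comp[, 2], fd = comp[, 3],
                            stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  class(truth) <- c("truth_table", "data.frame")

  # cell annotation: pseudotime uniform within each segment's slot, ordered
  # by segment along each branch; a single segment sits at pseudotime 0
  ann <- vector("list", k)
  set.seed(seeds[k + 1L])
  for (s in seq_len(k)) {
    m <- traj$cells_per_segment[s]
    br <- traj$branch[s]
    ord <- sum(traj$branch[seq_len(s)] == br)  # order within branch
    n_on_branch <- sum(traj$branch == br)
    pt <- if (n_on_branch == 1) rep(0, m) else
      stats::runif(m, (ord - 1) / n_on_branch, ord / n_on_branch)
    ann[[s]] <- data.frame(cell_id = sprintf("%s_cell%04d", segs[s],
                                             seq_len(m)),
                           cluster = segs[s], segment = segs[s],
                           branch = br, pseudotime = pt,
                           segment_order = ord, stringsAsFactors = FALSE)
  }
  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  list(truth = truth, annotation = annotation)
}

#' Write a 10x-style matrix directory
#'
#' Writes \code{matrix.mtx.gz} (MatrixMarket coordinate, integer,
#' 1-based), \code{features.tsv.gz} (id, name, "Gene Expression") and
#' \code{barcodes.tsv.gz} to \code{dir}. Round-trips losslessly through
#' [read_tenx()].
#'
#' @param counts Genes x cells matrix (sparse or dense, integer values).
#' @param dir Output directory (created if needed).
#' @param genes,barcodes Optional identifier vectors; default to the
#'   dimnames of \code{counts}.
#' @param gzip Write gzip-compressed files (default TRUE, the 10x v3
#'   convention).
#' @return Invisibly, the directory path.
#' @export
write_tenx <- function(counts, dir, genes = rownames(counts),
                       barcodes = colnames(counts), gzip = TRUE) {
  if (is.null(genes) || is.null(barcodes))
    stop("gene and barcode names are required")
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")
  stopifnot(nrow(counts) == length(genes), ncol(counts) == length(barcodes))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".gz" else ""
  opener <- if (gzip) gzfile else file
  ts <- Matrix::summary(counts)  # i, j, x triplets (1-based)
  con <- opener(file.path(dir, paste0("matrix.mtx", ext)), "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(counts), ncol(counts), nrow(ts))),
             con)
  if (nrow(ts))
    writeLines(sprintf("%d %d %d", ts$i, ts$j, as.integer(ts$x)), con)
  close(con)
  con <- opener(file.path(dir, paste0("features.tsv", ext)), "w")
  writeLines(paste(genes, genes, "Gene Expression", sep = "\t"), con)
  close(con)
  con <- opener(file.path(dir, paste0("barcodes.tsv", ext)), "w")
  writeLines(barcodes, con)
  close(con)
  invisible(dir)
}
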