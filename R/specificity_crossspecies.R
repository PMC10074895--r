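# Shannon-entropy expression specificity and cross-species cluster
# correlation via orthologs.

#' Shannon-entropy specificity index
#'
#' For a gene's per-group mean expression vector x, the cross-group profile
#' p = x / sum(x) has Shannon entropy H = -sum(p log2 p) (0 log 0 := 0).
#' The normalized index S = 1 - H / log2(n) lies in [0,1]: 0 for a uniform
#' profile, 1 for expression confined to a single group. Set
#' \code{normalized = FALSE} for the unnormalized variant log2(n) - H.
#'
#' @param x Nonnegative per-group mean expression, length >= 2, sum > 0.
#' @param normalized Return S in [0,1] (default) or log2(n) - H.
#' @return A list with \code{S}, \code{H} (bits), \code{n_groups}.
#' @examples
#' shannon_specificity(rep(1, 8))$S           # 0
#' shannon_specificity(c(1, 0, 0, 0))$S       # 1
#' @export
shannon_specificity <- function(x, normalized = TRUE) {
  if (length(x) < 2) stop("need at least 2 groups")
  if (any(x < 0)) stop("expression values must be nonnegative")
  if (sum(x) == 0) stop("all-zero profile: specificity undefined")
  p <- x / sum(x)
  nz <- p > 0
  H <- -sum(p[nz] * log2(p[nz]))
  S <- if (normalized) 1 - H / log2(length(x)) else log2(length(x)) - H
  list(S = S, H = H, n_groups = length(x))
}

#' Specificity scores for every gene of a grouped matrix
#'
#' @param expr Genes x groups nonnegative matrix.
#' @param normalized See [shannon_specificity()].
#' @return Data.frame (gene, S, H, peak_group); genes with all-zero
#'   profiles get NA scores.
#' @export
specificity_scores <- function(expr, normalized = TRUE) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("need at least 2 groups")
  tot <- rowSums(expr)
  S <- H <- rep(NA_real_, nrow(expr))
  ok <- tot > 0 & !apply(expr < 0, 1, any)
  if (any(expr < 0)) stop("expression values must be nonnegative")
  p <- expr[ok, , drop = FALSE] / tot[ok]
  plogp <- p * log2(p)
  plogp[p == 0] <- 0
  H[ok] <- -rowSums(plogp)
  S[ok] <- if (normalized) 1 - H[ok] / log2(ncol(expr)) else
    log2(ncol(expr)) - H[ok]
  peak <- colnames(expr)[max.col(expr, ties.method = "first")]
  data.frame(gene = rownames(expr), S = S, H = H, peak_group = peak,
             stringsAsFactors = FALSE)
}

#' Most group-specific gene per group
#'
#' A gene "peaks" in the group where its mean expression is maximal
#' (first-column tie-break); per group the peaking gene with the highest
#' specificity index is reported, ties broken by gene id order.
#'
#' @param expr Genes x groups nonnegative matrix.
#' @param gene_subset Optional gene ids to restrict to (e.g. lncRNAs).
#' @return Data.frame (group, gene, S); NA row for groups in which no gene
#'   peaks.
#' @export
top_specific_per_group <- function(expr, gene_subset = NULL) {
  expr <- as.matrix(expr)
  if (!is.null(gene_subset))
    expr <- expr[rownames(expr) %in% gene_subset, , drop = FALSE]
  sc <- specificity_scores(expr)
  rows <- lapply(colnames(expr), function(g) {
    cand <- sc[sc$peak_group == g & !is.na(sc$S), ]
    if (!nrow(cand))
      return(data.frame(group = g, gene = NA_character_, S = NA_real_,
                        stringsAsFactors = FALSE))
    cand <- cand[order(-cand$S, cand$gene), ]
    data.frame(group = g, gene = cand$gene[1], S = cand$S[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Construct and validate an ortholog map
#'
#' @param pairs Data.frame with columns \code{gene1}, \code{gene2} (or the
#'   first two columns are taken as such). Self-pairs are rejected;
#'   duplicate pairs removed.
#' @return Validated data.frame of class \code{ortholog_map} with a
#'   \code{pair_id} column.
#' @export
ortholog_map <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("gene1", "gene2") %in% colnames(pairs)))
    colnames(pairs)[1:2] <- c("gene1", "gene2")
  pairs <- pairs[, c("gene1", "gene2")]
  if (any(pairs$gene1 == pairs$gene2))
    stop("self-pairs are not allowed in an ortholog map")
  pairs <- pairs[!duplicated(pairs), , drop = FALSE]
  pairs$pair_id <- paste(pairs$gene1, pairs$gene2, sep = "|")
  rownames(pairs) <- NULL
  class(pairs) <- c("ortholog_map", "data.frame")
  pairs
}

#' Re-index grouped expression by ortholog pair
#'
#' Restricts a gene-by-group matrix to genes present in the ortholog map
#' (side 1 uses \code{gene1}, side 2 \code{gene2}) and re-indexes rows by
#' pair id so two species' matrices share a common row index. Policy
#' \code{one_to_one} keeps only pairs whose gene (on the chosen side) maps
#' uniquely; \code{mean} keeps all pairs, so a multi-partner gene's row is
#' reused for each of its pairs.
#'
#' @param expr Genes x groups matrix for one species.
#' @param map An [ortholog_map()].
#' @param side 1 if \code{expr} genes match \code{gene1}, 2 for
#'   \code{gene2}.
#' @param policy "one_to_one" (default) or "mean".
#' @return Matrix indexed by \code{pair_id}; attribute
#'   \code{n_dropped_genes} counts map genes absent from \code{expr}.
#' @export
collapse_orthologs <- function(expr, map, side = 1,
                               policy = c("one_to_one", "mean")) {
  policy <- match.arg(policy)
  expr <- as.matrix(expr)
  gcol <- if (side == 1) map$gene1 else map$gene2
  present <- gcol %in% rownames(expr)
  n_dropped <- sum(!gcol %in% rownames(expr))
  map_use <- map[present, , drop = FALSE]
  gcol <- gcol[present]
  if (policy == "one_to_one") {
    multi <- names(which(table(gcol) > 1))
    keep <- !gcol %in% multi
    map_use <- map_use[keep, , drop = FALSE]
    gcol <- gcol[keep]
  }
  if (!nrow(map_use))
    stop("no ortholog-map genes found in the expression matrix")
  out <- expr[gcol, , drop = FALSE]
  rownames(out) <- map_use$pair_id
  attr(out, "n_dropped_genes") <- n_dropped
  out
}

#' Cross-species pairwise cluster correlation
#'
#' Spearman rank correlation between every cluster of species 1 and every
#' cluster of species 2 over a shared ortholog-pair row index (typically
#' restricted to orthologous marker genes), with two-sided asymptotic
#' p-values and Benjamini-Hochberg adjustment across all cluster pairs.
#' Pairs involving a constant vector give NA with a message.
#'
#' @param m1,m2 Ortholog-pair x cluster matrices sharing a row index (see
#'   [collapse_orthologs()]).
#' @param genes Optional row-id restriction (e.g. marker-union pairs).
#' @param alpha Significance level for the adjusted p-values.
#' @return A list of matrices \code{rho}, \code{p}, \code{p_adj},
#'   \code{significant} (clusters1 x clusters2), plus \code{n_genes} used.
#' @export
pairwise_cluster_correlation <- function(m1, m2, genes = NULL,
                                         alpha = 0.05) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  shared <- intersect(rownames(m1), rownames(m2))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) < 3)
    stop("need at least 3 shared rows to correlate (have ",
         length(shared), ")")
  m1 <- m1[shared, , drop = FALSE]; m2 <- m2[shared, , drop = FALSE]
  k1 <- ncol(m1); k2 <- ncol(m2)
  rho <- p <- matrix(NA_real_, k1, k2,
                     dimnames = list(colnames(m1), colnames(m2)))
  for (i in seq_len(k1)) for (j in seq_len(k2)) {
    x <- m1[, i]; y <- m2[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      message("constant profile in pair (", colnames(m1)[i], ", ",
              colnames(m2)[j], "): correlation undefined")
      next
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    rho[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  p_adj <- matrix(stats::p.adjust(as.vector(p), method = "BH"), k1, k2,
                  dimnames = dimnames(p))
  list(rho = rho, p = p, p_adj = p_adj,
       significant = !is.na(p_adj) & p_adj < alpha,
       n_genes = length(shared))
}

#' Overlapped orthologous marker counts between two species' clusters
#'
#' For every cluster pair, counts marker genes of the first cluster whose
#' orthologs are markers of the second cluster — the quantity annotated on
#' cross-species cluster-matching diagrams.
#'
#' @param markers1,markers2 Named lists: cluster -> marker gene ids.
#' @param map An [ortholog_map()] with species-1 genes in \code{gene1}.
#' @return Long data.frame (cluster1, cluster2, n_overlap), Sankey-ready.
#' @export
overlapped_marker_counts <- function(markers1, markers2, map) {
  rows <- list()
  for (c1 in names(markers1)) for (c2 in names(markers2)) {
    sub <- map[map$gene1 %in% markers1[[c1]] &
                 map$gene2 %in% markers2[[c2]], , drop = FALSE]
    rows[[paste(c1, c2)]] <- data.frame(
      cluster1 = c1, cluster2 = c2,
      n_overlap = length(unique(sub$gene1)), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
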