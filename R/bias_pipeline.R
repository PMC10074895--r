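# Pseudobulk aggregation and group-level bias summaries.

#' Per-group mean expression (pseudobulk)
#'
#' Aggregates a gene-by-cell count matrix into a gene-by-group matrix of
#' mean expression. In \code{cp10k} mode each cell is first scaled to
#' 10,000 total counts (cells with zero total stay zero, with a warning);
#' \code{raw_mean} averages raw counts. Column order follows first
#' appearance of each group in the annotation.
#'
#' @param counts Genes x cells matrix (sparse dgCMatrix or dense), with
#'   dimnames.
#' @param annotation Data.frame with columns \code{cell_id} and
#'   \code{cluster} (or a named character vector cell -> group).
#' @param normalization \code{"cp10k"} (default) or \code{"raw_mean"}.
#' @param group_col Annotation column holding the group label.
#' @return Dense numeric matrix, genes x groups.
#' @export
pseudobulk_means <- function(counts, annotation, normalization = c("cp10k",
                             "raw_mean"), group_col = "cluster") {
  normalization <- match.arg(normalization)
  if (is.data.frame(annotation)) {
    groups_by_cell <- stats::setNames(as.character(annotation[[group_col]]),
                                      annotation$cell_id)
  } else groups_by_cell <- annotation
  cells <- colnames(counts)
  if (is.null(cells)) stop("counts must have cell (column) names")
  missing <- setdiff(cells, names(groups_by_cell))
  if (length(missing))
    stop("cells missing from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)",
                                          length(missing) - 5))
  grp <- groups_by_cell[cells]
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                        "CsparseMatrix")
  if (normalization == "cp10k") {
    tot <- Matrix::colSums(counts)
    if (any(tot == 0))
      warning(sum(tot == 0), " cell(s) with zero total counts left at zero")
    sf <- ifelse(tot > 0, 1e4 / tot, 0)
    counts <- counts %*% Matrix::Diagonal(x = sf)
  }
  lev <- unique(grp)  # first-appearance order
  ind <- Matrix::sparseMatrix(i = seq_along(grp),
                              j = match(grp, lev),
                              x = 1, dims = c(length(grp), length(lev)))
  sizes <- Matrix::colSums(ind)
  if (any(sizes == 0)) stop("empty group(s) in annotation")
  out <- as.matrix(counts %*% ind %*% Matrix::Diagonal(x = 1 / sizes))
  dimnames(out) <- list(rownames(counts), lev)
  out
}

#' Classify triads in every group of a pseudobulk matrix
#'
#' Runs [classify_matrix()] once per column of \code{expr}.
#'
#' @inheritParams classify_matrix
#' @return Named list (one element per group) of bias-call data.frames.
#' @export
classify_groups <- function(expr, triads, min_total_expr = 0.5,
                            centroids = triad_centroids()) {
  expr <- as.matrix(expr)
  out <- lapply(colnames(expr), function(g)
    classify_matrix(expr, triads, g, min_total_expr, centroids))
  stats::setNames(out, colnames(expr))
}

#' Cluster-level fate of bulk-balanced triads
#'
#' Restricts to triads called Balance at the bulk level and reports, per
#' cluster, the distribution of their cluster-level categories. This is the
#' bulk-versus-single-cell comparison in which triads balanced in aggregate
#' turn out biased in individual cell types. Two denominators are emitted:
#' triads expressed in the cluster (used for the proportions) and all
#' bulk-balanced triads.
#'
#' @param bulk_calls Bias calls for the bulk/pooled sample
#'   ([classify_matrix()] output).
#' @param cluster_calls Named list of per-cluster calls
#'   ([classify_groups()] output).
#' @return A list: \code{breakdown} — long data.frame (group, category,
#'   count, proportion among expressed bulk-balanced triads);
#'   \code{unbalanced} — per-group data.frame with
#'   \code{n_bulk_balanced}, \code{n_expressed},
#'   \code{unbalanced_fraction} (1 - Balance proportion among expressed)
#'   and \code{unbalanced_fraction_all} (denominator = all bulk-balanced).
#' @export
balanced_breakdown <- function(bulk_calls, cluster_calls) {
  bal_ids <- bulk_calls$triad_id[bulk_calls$category == "Balance" &
                                   !is.na(bulk_calls$fa)]
  rows <- list(); unb <- list()
  for (g in names(cluster_calls)) {
    cc <- cluster_calls[[g]]
    if (!setequal(cc$triad_id, bulk_calls$triad_id))
      stop("cluster and bulk calls cover different triad sets (group ", g, ")")
    cc <- cc[cc$triad_id %in% bal_ids, ]
    expressed <- cc[cc$category != NOT_EXPRESSED, ]
    n_expr <- nrow(expressed)
    counts <- table(factor(as.character(expressed$category),
                           levels = TRIAD_CATEGORIES))
    prop <- if (n_expr > 0) as.numeric(counts) / n_expr else
      rep(NA_real_, 7)
    rows[[g]] <- data.frame(group = g, category = TRIAD_CATEGORIES,
                            count = as.integer(counts), proportion = prop,
                            stringsAsFactors = FALSE)
    n_unb <- n_expr - as.integer(counts["Balance"])
    unb[[g]] <- data.frame(group = g,
                           n_bulk_balanced = length(bal_ids),
                           n_expressed = n_expr,
                           unbalanced_fraction =
                             if (n_expr > 0) n_unb / n_expr else NA_real_,
                           unbalanced_fraction_all =
                             if (length(bal_ids) > 0)
                               n_unb / length(bal_ids) else NA_real_,
                           stringsAsFactors = FALSE)
  }
  list(breakdown = do.call(rbind, c(rows, make.row.names = FALSE)),
       unbalanced = do.call(rbind, c(unb, make.row.names = FALSE)))
}

#' Category counts and proportions per group
#'
#' Tallies the seven bias categories among expressed triads of each group —
#' the numbers behind a stacked-histogram view of cell-type-specific
#' asymmetric expression. Proportions use expressed triads as denominator;
#' the \code{not_expressed} count is carried alongside so that per group
#' category counts + not_expressed always equals the triad-table size.
#'
#' @param calls Named list of bias-call data.frames ([classify_groups()]).
#' @return Long data.frame: group, category (7 labels + not_expressed),
#'   count, proportion (NA for not_expressed rows and for groups with no
#'   expressed triads).
#' @export
category_proportions <- function(calls) {
  stopifnot(length(calls) >= 1)
  rows <- lapply(names(calls), function(g) {
    cc <- calls[[g]]
    counts <- table(factor(as.character(cc$category),
                           levels = c(TRIAD_CATEGORIES, NOT_EXPRESSED)))
    n_expr <- sum(counts[TRIAD_CATEGORIES])
    prop <- c(if (n_expr > 0) as.numeric(counts[TRIAD_CATEGORIES]) / n_expr
              else rep(NA_real_, 7), NA_real_)
    data.frame(group = g,
               category = c(TRIAD_CATEGORIES, NOT_EXPRESSED),
               count = as.integer(counts), proportion = prop,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Suppressed-to-dominant ratio for one subgenome
#'
#' count(g.suppressed) / count(g.dominant) within a group; a one-number
#' summary of whether losing a subgenome's copy is more common than that
#' copy dominating. Zero dominant count yields \code{Inf} with a warning
#' rather than an error, since small clusters can legitimately lack
#' dominant calls.
#'
#' @param summary Output of [category_proportions()].
#' @param subgenome One of "A", "B", "D".
#' @param group Group label present in \code{summary}.
#' @return A single numeric ratio.
#' @export
suppressed_dominant_ratio <- function(summary, subgenome = c("A", "B", "D"),
                                      group) {
  subgenome <- match.arg(subgenome)
  s <- summary[summary$group == group, ]
  if (!nrow(s)) stop("group not found in summary: ", group)
  sup <- s$count[s$category == paste0(subgenome, ".suppressed")]
  dom <- s$count[s$category == paste0(subgenome, ".dominant")]
  if (dom == 0) {
    warning("zero ", subgenome, ".dominant triads in group ", group,
            "; returning Inf")
    return(Inf)
  }
  sup / dom
}

#' All six suppressed/dominant ratios per group
#'
#' @param summary Output of [category_proportions()].
#' @return Data.frame (group, subgenome, n_suppressed, n_dominant, ratio).
#' @export
suppressed_dominant_table <- function(summary) {
  groups <- unique(summary$group)
  rows <- list()
  for (g in groups) for (sg in c("A", "B", "D")) {
    s <- summary[summary$group == g, ]
    sup <- s$count[s$category == paste0(sg, ".suppressed")]
    dom <- s$count[s$category == paste0(sg, ".dominant")]
    rows[[paste(g, sg)]] <- data.frame(
      group = g, subgenome = sg, n_suppressed = sup, n_dominant = dom,
      ratio = if (dom > 0) sup / dom else Inf, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Bias of marker-gene triads per cluster
#'
#' A triad counts as a marker triad for a cluster if any of its three
#' homoeologs is in that cluster's marker list. For each cluster the
#' fraction of its marker triads (expressed in that cluster) with a
#' non-Balance category is reported; markers not in any triad are counted
#' and dropped.
#'
#' @param cluster_calls Named list of per-cluster bias calls.
#' @param marker_sets Named list: cluster -> character vector of marker
#'   gene ids.
#' @param triads A [triad_table()].
#' @return Data.frame (group, n_markers, n_markers_in_triads,
#'   n_marker_triads expressed, fraction_unbalanced; NA when no expressed
#'   marker triads).
#' @export
marker_bias_summary <- function(cluster_calls, marker_sets, triads) {
  gene2triad <- stats::setNames(
    rep(triads$triad_id, 3),
    c(triads$gene_a, triads$gene_b, triads$gene_d))
  rows <- lapply(names(marker_sets), function(g) {
    mk <- unique(marker_sets[[g]])
    if (!length(mk) || !g %in% names(cluster_calls))
      return(data.frame(group = g, n_markers = length(mk),
                        n_markers_in_triads = 0L, n_marker_triads = 0L,
                        fraction_unbalanced = NA_real_,
                        stringsAsFactors = FALSE))
    hit <- mk[mk %in% names(gene2triad)]
    tri <- unique(gene2triad[hit])
    cc <- cluster_calls[[g]]
    cc <- cc[cc$triad_id %in% tri & cc$category != NOT_EXPRESSED, ]
    frac <- if (nrow(cc) > 0) mean(cc$category != "Balance") else NA_real_
    data.frame(group = g, n_markers = length(mk),
               n_markers_in_triads = length(hit),
               n_marker_triads = nrow(cc),
               fraction_unbalanced = frac, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
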