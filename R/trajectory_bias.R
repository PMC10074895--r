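# Asymmetric expression along pseudotime trajectories.

#' Group trajectory cells into ordered segments
#'
#' Either passes provided segment labels through (\code{mode = "labels"}) or
#' splits each branch into k equal-count pseudotime bins
#' (\code{mode = "bins"}). Boundary ties are broken deterministically by
#' cell id order.
#'
#' @param annotation Data.frame with \code{cell_id}; \code{segment} and
#'   \code{branch} columns for labels mode; \code{pseudotime} (and optional
#'   \code{branch}) for binning.
#' @param mode "labels" or "bins".
#' @param k Number of bins per branch (binning mode).
#' @return Data.frame (cell_id, branch, segment, segment_order); segments
#'   ordered along each branch.
#' @export
segment_cells <- function(annotation, mode = c("labels", "bins"), k = 4L) {
  mode <- match.arg(mode)
  if (is.null(annotation$branch)) annotation$branch <- "branch1"
  if (mode == "labels") {
    if (is.null(annotation$segment))
      stop("labels mode requires a segment column")
    ord <- if (!is.null(annotation$segment_order)) annotation$segment_order
      else {
        # order of first appearance within branch
        ave(seq_len(nrow(annotation)), annotation$branch,
            FUN = function(i) match(annotation$segment[i],
                                    unique(annotation$segment[i])))
      }
    return(data.frame(cell_id = annotation$cell_id,
                      branch = annotation$branch,
                      segment = annotation$segment,
                      segment_order = as.integer(ord),
                      stringsAsFactors = FALSE))
  }
  if (is.null(annotation$pseudotime))
    stop("binning mode requires a pseudotime column")
  out <- lapply(split(annotation, annotation$branch), function(br) {
    if (k > nrow(br))
      stop("k = ", k, " exceeds the ", nrow(br), " cells on branch ",
           br$branch[1])
    o <- order(br$pseudotime, br$cell_id)
    bin <- ceiling(seq_along(o) / (nrow(br) / k))
    bin <- pmin(bin, k)
    data.frame(cell_id = br$cell_id[o], branch = br$branch[o],
               segment = sprintf("%s_bin%02d", br$branch[o], bin),
               segment_order = as.integer(bin), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  out[order(match(out$cell_id, annotation$cell_id)), , drop = FALSE]
}

#' Fraction of asymmetric triads along a trajectory
#'
#' Per trajectory segment: pseudobulk the segment's cells, classify every
#' triad, and report the fraction of expressed triads with a non-Balance
#' category. Rows are ordered start-to-terminal within each branch, giving
#' the unbalanced-fraction profile along differentiation.
#'
#' @param counts Genes x cells matrix.
#' @param segments Output of [segment_cells()].
#' @param triads A [triad_table()].
#' @param min_total_expr Expression floor, see [classify_matrix()].
#' @param normalization Pseudobulk mode, see [pseudobulk_means()].
#' @param centroids Centroid matrix.
#' @return Data.frame (branch, segment, segment_order, n_cells,
#'   n_expressed_triads, unbalanced_fraction), ordered by branch then
#'   segment order. Segments with no cells yield an NA row.
#' @export
asymmetry_along_trajectory <- function(counts, segments, triads,
                                       min_total_expr = 0.5,
                                       normalization = "cp10k",
                                       centroids = triad_centroids()) {
  ann <- data.frame(cell_id = segments$cell_id, cluster = segments$segment,
                    stringsAsFactors = FALSE)
  pb <- pseudobulk_means(counts[, segments$cell_id, drop = FALSE], ann,
                         normalization = normalization)
  seg_info <- unique(segments[, c("branch", "segment", "segment_order")])
  seg_info <- seg_info[order(seg_info$branch, seg_info$segment_order), ]
  rows <- lapply(seq_len(nrow(seg_info)), function(i) {
    s <- seg_info$segment[i]
    n_cells <- sum(segments$segment == s)
    if (n_cells == 0 || !s %in% colnames(pb))
      return(data.frame(branch = seg_info$branch[i], segment = s,
                        segment_order = seg_info$segment_order[i],
                        n_cells = n_cells, n_expressed_triads = 0L,
                        unbalanced_fraction = NA_real_,
                        stringsAsFactors = FALSE))
    calls <- classify_matrix(pb, triads, s, min_total_expr, centroids)
    expr <- calls[calls$category != NOT_EXPRESSED, ]
    data.frame(branch = seg_info$branch[i], segment = s,
               segment_order = seg_info$segment_order[i],
               n_cells = n_cells, n_expressed_triads = nrow(expr),
               unbalanced_fraction =
                 if (nrow(expr)) mean(expr$category != "Balance")
                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
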