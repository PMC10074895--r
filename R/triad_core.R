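# The seven printed category labels, in tie-break priority order:
# Balance first (bias toward the null category), then dominants, then
# suppressed, each in A/B/D order.
TRIAD_CATEGORIES <- c("Balance",
                      "A.dominant", "B.dominant", "D.dominant",
                      "A.suppressed", "B.suppressed", "D.suppressed")

NOT_EXPRESSED <- "not_expressed"

#' Ideal bias-category centroids on the 2-simplex
#'
#' Returns the seven ideal (fA, fB, fD) points used by the nearest-centroid
#' classifier. \code{Balance} is the uniform point; each dominant category
#' puts all expression on one subgenome; each suppressed category silences
#' one subgenome and splits the remainder equally. These are the unique
#' ideal compositions implied by the category names and are the package
#' defaults; pass a modified copy to the classifiers to change them.
#'
#' @return A 7 x 3 numeric matrix; rows named by category
#'   (Balance, A.dominant, B.dominant, D.dominant, A.suppressed,
#'   B.suppressed, D.suppressed), columns \code{fa}, \code{fb}, \code{fd}.
#'   Every row sums to 1.
#' @examples
#' triad_centroids()["Balance", ]
#' @export
triad_centroids <- function() {
  m <- rbind(
    Balance        = c(1/3, 1/3, 1/3),
    A.dominant     = c(1,   0,   0),
    B.dominant     = c(0,   1,   0),
    D.dominant     = c(0,   0,   1),
    A.suppressed   = c(0,   1/2, 1/2),
    B.suppressed   = c(1/2, 0,   1/2),
    D.suppressed   = c(1/2, 1/2, 0)
  )
  colnames(m) <- c("fa", "fb", "fd")
  m
}

validate_centroids <- function(centroids) {
  stopifnot(is.matrix(centroids), ncol(centroids) == 3, nrow(centroids) >= 1)
  if (any(centroids < 0) || any(abs(rowSums(centroids) - 1) > 1e-9))
    stop("centroids must be valid simplex compositions (nonnegative, rows sum to 1)")
  if (is.null(rownames(centroids)) || anyDuplicated(rownames(centroids)))
    stop("centroids must have unique row names (category labels)")
  centroids
}

#' Load a homoeolog triad table
#'
#' Reads a tab-separated triad table (header required) listing, per triad,
#' one gene from each of the A, B and D subgenomes. Incomplete rows (any
#' missing role) are dropped and counted; duplicated triads are removed
#' deterministically (first occurrence wins). A gene identifier appearing in
#' more than one triad or more than one role is a validation error.
#'
#' @param path Path to a TSV file with a header row.
#' @param column_map Named character vector mapping the roles
#'   \code{triad_id}, \code{gene_a}, \code{gene_b}, \code{gene_d} to column
#'   names in the file. Defaults to columns \code{triad_id}, \code{A},
#'   \code{B}, \code{D}.
#' @param quiet Suppress the kept/dropped message.
#' @return A \code{data.frame} of class \code{triad_table} with columns
#'   \code{triad_id}, \code{gene_a}, \code{gene_b}, \code{gene_d}.
#' @export
load_triad_table <- function(path,
                             column_map = c(triad_id = "triad_id",
                                            gene_a = "A", gene_b = "B",
                                            gene_d = "D"),
                             quiet = FALSE) {
  if (!file.exists(path)) stop("triad table not found: ", path)
  defaults <- c(triad_id = "triad_id", gene_a = "A", gene_b = "B", gene_d = "D")
  cm <- defaults
  cm[names(column_map)] <- column_map
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(cm), colnames(raw))
  if (length(missing_cols))
    stop("triad table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- data.frame(triad_id = as.character(raw[[cm["triad_id"]]]),
                   gene_a = as.character(raw[[cm["gene_a"]]]),
                   gene_b = as.character(raw[[cm["gene_b"]]]),
                   gene_d = as.character(raw[[cm["gene_d"]]]),
                   stringsAsFactors = FALSE)
  n_in <- nrow(df)
  complete <- !Reduce(`|`, lapply(df, function(x) is.na(x) | x == ""))
  df <- df[complete, , drop = FALSE]
  dup <- duplicated(df$triad_id)
  df <- df[!dup, , drop = FALSE]
  n_dropped <- n_in - nrow(df)
  if (!quiet)
    message(sprintf("triad table: kept %d of %d records (%d dropped)",
                    nrow(df), n_in, n_dropped))
  triad_table(df)
}

#' Construct and validate a triad table
#'
#' @param df A data.frame with columns \code{triad_id}, \code{gene_a},
#'   \code{gene_b}, \code{gene_d}.
#' @return The validated data.frame with class \code{triad_table}.
#' @export
triad_table <- function(df) {
  req <- c("triad_id", "gene_a", "gene_b", "gene_d")
  if (!all(req %in% colnames(df)))
    stop("triad table needs columns: ", paste(req, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)[, req]
  if (anyDuplicated(df$triad_id))
    stop("duplicate triad_id values: ",
         paste(unique(df$triad_id[duplicated(df$triad_id)]), collapse = ", "))
  genes <- c(df$gene_a, df$gene_b, df$gene_d)
  if (anyDuplicated(genes)) {
    offenders <- unique(genes[duplicated(genes)])
    stop("gene identifier(s) present in more than one triad or role: ",
         paste(utils::head(offenders, 10), collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("triad_table", "data.frame")
  df
}

#' Normalize triad expression onto the 2-simplex
#'
#' Divides each (a, b, d) expression triple by its sum so the three
#' fractions sum to 1. Scale-invariant: any positive rescaling of the
#' inputs gives the same composition.
#'
#' @param a,b,d Nonnegative expression values (vectors of equal length).
#' @return A numeric matrix with columns \code{fa}, \code{fb}, \code{fd};
#'   one row per input triple, each row summing to 1.
#' @examples
#' normalize_triads(2, 1, 1)   # 0.5 0.25 0.25
#' @export
normalize_triads <- function(a, b, d) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE) ||
      any(d < 0, na.rm = TRUE))
    stop("negative expression values are not allowed")
  total <- a + b + d
  if (any(total == 0, na.rm = TRUE))
    stop("triad not expressed: a + b + d is zero; filter zero-total triads first")
  cbind(fa = a / total, fb = b / total, fd = d / total)
}

#' Euclidean distance between simplex compositions
#'
#' Plain 3-component Euclidean distance between two (fa, fb, fd) points;
#' no projection to 2-D is applied.
#'
#' @param p,q Numeric length-3 compositions, or matrices with 3 columns
#'   (rowwise distance).
#' @return Nonnegative distance(s).
#' @export
composition_distance <- function(p, q) {
  p <- rbind(p); q <- rbind(q)
  unname(sqrt(rowSums((p - q)^2)))
}

# Squared distances of an n x 3 composition matrix to each centroid row.
.centroid_dist2 <- function(comp, centroids) {
  # ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2, vectorized over both
  xx <- rowSums(comp^2)
  cc <- rowSums(centroids^2)
  d2 <- outer(xx, cc, `+`) - 2 * comp %*% t(centroids)
  pmax(d2, 0)
}

#' Classify simplex compositions into the seven bias categories
#'
#' Assigns each composition to the category whose ideal centroid is nearest
#' in Euclidean distance. Exact ties (within \code{tol} on squared distance)
#' are broken by centroid row order — with the default centroids, Balance
#' first, then A/B/D dominant, then A/B/D suppressed.
#'
#' @param comp Numeric matrix with columns (fa, fb, fd), rows summing to 1,
#'   or a single length-3 composition.
#' @param centroids Centroid matrix as from [triad_centroids()].
#' @param tol Squared-distance tolerance within which two centroids count
#'   as tied.
#' @return A data.frame with columns \code{category} (factor over the
#'   centroid labels) and \code{distance}.
#' @examples
#' classify_compositions(c(1/3, 1/3, 1/3))          # Balance, distance 0
#' classify_compositions(c(0.5, 0.3, 0.2))
#' @export
classify_compositions <- function(comp, centroids = triad_centroids(),
                                  tol = 1e-12) {
  centroids <- validate_centroids(centroids)
  comp <- rbind(comp)
  if (ncol(comp) != 3) stop("compositions must have 3 components")
  if (any(comp < -1e-9) || any(abs(rowSums(comp) - 1) > 1e-9))
    stop("rows must be valid compositions (nonnegative, summing to 1)")
  d2 <- .centroid_dist2(comp, centroids)
  best <- apply(d2, 1L, function(r) which(r <= min(r) + tol)[1L])
  data.frame(category = factor(rownames(centroids)[best],
                               levels = rownames(centroids)),
             distance = sqrt(d2[cbind(seq_len(nrow(comp)), best)]))
}

#' Classify all triads of one expression group
#'
#' Looks up the three homoeolog genes of every triad in one column (group)
#' of a gene-by-group mean-expression matrix, filters triads whose total
#' expression is at or below \code{min_total_expr} (labelled
#' \code{not_expressed}), normalizes the rest onto the simplex, and runs the
#' nearest-centroid classifier. Genes absent from the matrix count as zero
#' expression.
#'
#' @param expr Numeric matrix, rows = genes (named), columns = groups (named).
#' @param triads A [triad_table()].
#' @param group Column name in \code{expr}.
#' @param min_total_expr Total-expression floor; triads with
#'   a + b + d <= this value are reported as \code{not_expressed}. Default
#'   0.5 in the mean-expression units of \code{expr}.
#' @param centroids Centroid matrix, see [triad_centroids()].
#' @return A data.frame with one row per triad (same order as
#'   \code{triads}): \code{triad_id}, \code{group}, \code{fa}, \code{fb},
#'   \code{fd}, \code{category}, \code{distance}. Composition and distance
#'   are \code{NA} for \code{not_expressed} triads.
#' @export
classify_matrix <- function(expr, triads, group, min_total_expr = 0.5,
                            centroids = triad_centroids()) {
  expr <- as.matrix(expr)
  if (!group %in% colnames(expr))
    stop("group not found in expression matrix: ", group)
  v <- expr[, group]
  if (any(v < 0)) stop("expression matrix has negative entries")
  pick <- function(g) ifelse(g %in% names(v), unname(v[g]), 0)
  a <- pick(triads$gene_a); b <- pick(triads$gene_b); d <- pick(triads$gene_d)
  total <- a + b + d
  expressed <- total > min_total_expr
  out <- data.frame(triad_id = triads$triad_id,
                    group = group,
                    fa = NA_real_, fb = NA_real_, fd = NA_real_,
                    category = factor(NOT_EXPRESSED,
                                      levels = c(rownames(centroids),
                                                 NOT_EXPRESSED)),
                    distance = NA_real_,
                    stringsAsFactors = FALSE)
  if (any(expressed)) {
    comp <- normalize_triads(a[expressed], b[expressed], d[expressed])
    cls <- classify_compositions(comp, centroids)
    out$fa[expressed] <- comp[, "fa"]
    out$fb[expressed] <- comp[, "fb"]
    out$fd[expressed] <- comp[, "fd"]
    out$category[expressed] <- as.character(cls$category)
    out$distance[expressed] <- cls$distance
  }
  out
}

#' Ternary plot coordinates for classified triads
#'
#' Extracts the plot-ready (fa, fb, fd, category) table of expressed triads
#' from a set of bias calls, suitable for any ternary plotting tool.
#'
#' @param calls Output of [classify_matrix()] (or rows bound from several
#'   groups).
#' @return A data.frame with columns \code{triad_id}, \code{fa}, \code{fb},
#'   \code{fd}, \code{category}; \code{not_expressed} rows are dropped.
#' @export
ternary_coordinates <- function(calls) {
  keep <- !is.na(calls$fa) & calls$category != NOT_EXPRESSED
  out <- calls[keep, c("triad_id", "fa", "fb", "fd", "category")]
  out$category <- as.character(out$category)
  rownames(out) <- NULL
  out
}
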