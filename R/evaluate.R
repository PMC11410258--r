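#' Exact k-nearest-neighbour sets for every cell
#'
#' Computes the exact (non-approximate) k nearest neighbours of each cell
#' (column) under Euclidean distance in the given feature space. Distance
#' ties are broken deterministically towards the lower cell index, and a
#' cell is never its own neighbour.
#'
#' @param x genes x cells matrix of expression values (raw counts, a plain
#'   matrix, or a `transformed_matrix`).
#' @param k number of neighbours per cell; must be smaller than the number
#'   of cells.
#' @param metric distance metric; only `"euclidean"` is provided.
#' @return object of class `knn_sets`: list with `k`, `n_cells` and
#'   `neighbors`, an `n_cells` x `k` integer matrix of neighbour indices
#'   (row i = the k nearest cells to cell i, nearest first).
#' @export
#' @examples
#' m <- matrix(c(0, 1, 10), 1, 3,
#'             dimnames = list("g1", c("a", "b", "c")))
#' knn_sets(m, k = 1)$neighbors
knn_sets <- function(x, k, metric = "euclidean") {
  metric <- match.arg(metric)
  v <- as.matrix(transform_values(x))
  n <- ncol(v)
  if (length(k) != 1L || is.na(k) || k < 1 || k >= n) {
    abort("`k` must satisfy 1 <= k < number of cells",
          class = "ddg_parameter_error")
  }
  sq <- colSums(v^2)
  neighbors <- matrix(0L, n, k)
  block <- max(1L, min(n, as.integer(ceiling(4e6 / n))))
  for (start in seq(1L, n, by = block)) {
    cols <- start:min(start + block - 1L, n)
    # squared distances via the inner-product expansion; bitwise-identical
    # columns give bitwise-identical rows, so ties stay exact
    g <- crossprod(v[, cols, drop = FALSE], v)
    d2 <- sweep(-2 * g, 2, sq, "+") + sq[cols]
    for (i in seq_along(cols)) {
      cell <- cols[i]
      ord <- order(d2[i, ], seq_len(n))
      ord <- ord[ord != cell]
      neighbors[cell, ] <- ord[seq_len(k)]
    }
  }
  structure(list(k = as.integer(k), n_cells = n, neighbors = neighbors),
            class = "knn_sets")
}

#' @export
print.knn_sets <- function(x, ...) {
  cat(sprintf("# k-NN sets: %d cells, k = %d\n", x$n_cells, x$k))
  invisible(x)
}

#' Average Jaccard distance between two neighbourhood structures
#'
#' For every cell, the Jaccard distance `1 - |A ∩ B| / |A ∪ B|` between its
#' k-NN set in space A and in space B, averaged over cells. 0 means all
#' neighbourhoods are preserved; 1 means no original neighbour remains -
#' a direct measure of the distortion introduced by feature selection or
#' dimensionality reduction.
#'
#' @param a,b `knn_sets` objects over the same cells with the same k.
#' @return a single value in `[0, 1]`.
#' @export
average_jaccard_distance <- function(a, b) {
  stopifnot(inherits(a, "knn_sets"), inherits(b, "knn_sets"))
  if (a$n_cells != b$n_cells || a$k != b$k) {
    abort("neighbourhood sets differ in cell count or k",
          class = "ddg_parameter_error")
  }
  per_cell <- vapply(seq_len(a$n_cells), function(i) {
    na <- a$neighbors[i, ]
    nb <- b$neighbors[i, ]
    inter <- length(intersect(na, nb))
    1 - inter / (2 * a$k - inter)
  }, numeric(1))
  mean(per_cell)
}

#' Jaccard index between two feature sets
#'
#' `|A ∩ B| / |A ∪ B|`, the size-adjusted overlap between two gene sets;
#' defined as 0 when both sets are empty.
#'
#' @param a,b character vectors of gene ids (duplicates ignored).
#' @return a single value in `[0, 1]`.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  union_size <- length(union(a, b))
  if (union_size == 0) return(0)
  length(intersect(a, b)) / union_size
}

#' Fraction of a ground-truth set recovered by a prediction
#'
#' `|predicted ∩ truth| / |truth|` - the recall of a feature selection
#' against a known set of truly variable genes.
#'
#' @param predicted character vector of predicted gene ids.
#' @param truth character vector of ground-truth gene ids; must be nonempty.
#' @return a single value in `[0, 1]`.
#' @export
recovery_fraction <- function(predicted, truth) {
  truth <- unique(truth)
  if (length(truth) == 0) {
    abort("`truth` must be nonempty", class = "ddg_parameter_error")
  }
  length(intersect(unique(predicted), truth)) / length(truth)
}

#' Supervised differential-expression reference set (Wilcoxon rank-sum)
#'
#' With cell-type labels known a priori, genes whose means differ across
#' groups form a supervised reference for what a feature selection should
#' find. For every gene, each group is tested one-vs-rest with the Wilcoxon
#' rank-sum test on raw counts; the per-gene p-value is the minimum across
#' groups times the number of groups (Bonferroni within gene), then
#' Benjamini-Hochberg across genes at `fdr`.
#'
#' @param counts genes x cells count matrix.
#' @param labels per-cell group labels: a character/factor vector aligned to
#'   the columns, or a tibble with `cell_id` and `label` columns matching
#'   the matrix barcodes.
#' @param fdr false discovery rate for the BH step (default 0.01).
#' @return tibble with one row per gene: `gene_id`, `p_value`, `q_value`,
#'   `significant`.
#' @seealso [wilcoxon_de_set()] for just the significant gene ids.
#' @export
wilcoxon_de <- function(counts, labels, fdr = 0.01) {
  validate_counts(counts)
  labels <- align_labels(labels, colnames(counts))
  groups <- split(seq_along(labels), labels)
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    abort("need >= 2 label groups with >= 2 cells each",
          class = "ddg_parameter_error")
  }
  v <- as.matrix(counts)
  n_groups <- length(groups)
  p_gene <- vapply(seq_len(nrow(v)), function(i) {
    x <- v[i, ]
    p_min <- 1
    for (idx in groups) {
      p <- suppressWarnings(
        wilcox.test(x[idx], x[-idx], exact = FALSE)$p.value)
      if (!is.finite(p)) p <- 1  # constant gene: no rank information
      if (p < p_min) p_min <- p
    }
    min(p_min * n_groups, 1)
  }, numeric(1))
  q <- bh_qvalues(p_gene)
  tibble(gene_id = rownames(counts), p_value = p_gene, q_value = q,
         significant = q <= fdr)
}

#' @rdname wilcoxon_de
#' @return for `wilcoxon_de_set()`: character vector of significant gene ids.
#' @export
wilcoxon_de_set <- function(counts, labels, fdr = 0.01) {
  de <- wilcoxon_de(counts, labels, fdr = fdr)
  de$gene_id[de$significant]
}

#' Adjusted Rand index between two cell partitions
#'
#' Chance-corrected agreement between two labelings of the same cells,
#' computed from the pair-counting contingency table (permutation-model
#' adjustment, via [mclust::adjustedRandIndex()]). 1 for identical
#' partitions up to label names; expectation ~0 for independent ones.
#'
#' @param a,b partitions: character/factor vectors of equal length, or
#'   tibbles with `cell_id` and `label` (matched on `cell_id`).
#' @return a single value (<= 1).
#' @export
adjusted_rand_index <- function(a, b) {
  if (is.data.frame(a) && is.data.frame(b)) {
    ids <- a$cell_id
    b <- align_labels(b, ids)
    a <- align_labels(a, ids)
  }
  if (length(a) != length(b)) {
    abort("partitions have different lengths", class = "ddg_parameter_error")
  }
  mclust::adjustedRandIndex(as.character(a), as.character(b))
}

align_labels <- function(labels, cell_ids) {
  if (is.data.frame(labels)) {
    if (!all(c("cell_id", "label") %in% names(labels))) {
      abort("label frame needs `cell_id` and `label` columns",
            class = "ddg_format_error")
    }
    idx <- match(cell_ids, labels$cell_id)
    if (anyNA(idx)) {
      abort("labels missing for some cells", class = "ddg_format_error")
    }
    return(as.character(labels$label[idx]))
  }
  if (length(labels) != length(cell_ids)) {
    abort("labels and cells differ in length", class = "ddg_format_error")
  }
  as.character(labels)
}
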