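#' Highly variable gene baseline (binned-dispersion z-score)
#'
#' The dispersion-based feature selection that dominates standard pipelines:
#' counts are CPM-normalized and log(1+x)-transformed, a per-gene mean and
#' dispersion (variance/mean) are computed on the transformed values, genes
#' are binned into `n_bins` equal-count bins by mean expression, the
#' dispersion is z-scored within each bin, and the `n_top` genes with the
#' highest z-scores are returned. This flags genes with higher variance than
#' expected given their average count - with no model of technical noise.
#'
#' Only genes with at least one count are eligible. Bins with a single gene
#' or zero dispersion spread get z-score 0. Ties are broken by input gene
#' order so the selection is deterministic.
#'
#' @param counts genes x cells count matrix.
#' @param n_top number of genes to select; at most the number of genes with
#'   nonzero counts.
#' @param n_bins number of equal-count mean-expression bins (default 20).
#' @return character vector of `n_top` gene ids, ranked by z-score.
#' @export
#' @examples
#' sim <- simulate_gmm(cells_per_type = 100, n_genes = 60, markers_per_type = 15,
#'                     capture_p = 0.05, seed = 1)
#' head(select_hvgs(sim$observed, n_top = 10))
select_hvgs <- function(counts, n_top, n_bins = 20) {
  validate_counts(counts)
  # canonicalize the storage class: z-score ranking resolves near-ties, so
  # the dense and sparse accumulation paths must round identically
  if (!is(counts, "sparseMatrix")) {
    counts <- as(as(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                    "CsparseMatrix"), "generalMatrix")
  }
  tm <- log1p_transform(cpm_normalize(counts))
  v <- tm$values
  n <- ncol(v)
  row_sum <- Matrix::rowSums(v)
  row_sq <- Matrix::rowSums(v * v)
  mean_t <- row_sum / n
  var_t <- pmax(row_sq / n - mean_t^2, 0)

  eligible <- Matrix::rowSums(counts) > 0
  if (length(n_top) != 1L || is.na(n_top) || n_top < 1 || n_top > sum(eligible)) {
    abort(sprintf(
      "`n_top` must be between 1 and the number of genes with nonzero counts (%d)",
      sum(eligible)), class = "ddg_parameter_error")
  }

  stats <- tibble(
    gene_id = rownames(counts),
    order = seq_len(nrow(counts)),
    mean = mean_t,
    dispersion = ifelse(mean_t > 0, var_t / mean_t, NA_real_)
  )[eligible, ]
  stats$bin <- dplyr::ntile(stats$mean, min(n_bins, nrow(stats)))
  stats <- dplyr::mutate(
    dplyr::group_by(stats, .data$bin),
    z = if (dplyr::n() < 2 || sd(.data$dispersion) == 0) 0
        else (.data$dispersion - mean(.data$dispersion)) / sd(.data$dispersion)
  )
  stats <- dplyr::ungroup(stats)
  stats <- stats[order(-stats$z, stats$order), ]
  stats$gene_id[seq_len(n_top)]
}
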