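#' Transformed expression matrices
#'
#' The standard-pipeline transforms ([cpm_normalize()], [log1p_transform()])
#' return a light container holding the real-valued genes x cells matrix and
#' the ordered list of transforms that produced it, so downstream code can
#' tell raw counts from normalized values.
#'
#' @param values real genes x cells matrix.
#' @param provenance character vector of transform names, in order applied.
#' @return object of class `transformed_matrix`.
#' @keywords internal
new_transformed_matrix <- function(values, provenance) {
  structure(list(values = values, provenance = provenance),
            class = "transformed_matrix")
}

#' @export
print.transformed_matrix <- function(x, ...) {
  cat(sprintf("# transformed matrix: %d genes x %d cells [%s]\n",
              nrow(x$values), ncol(x$values),
              paste(x$provenance, collapse = " -> ")))
  invisible(x)
}

# accept raw counts, plain matrices or a transformed_matrix
transform_values <- function(x) {
  if (inherits(x, "transformed_matrix")) x$values else x
}

transform_provenance <- function(x) {
  if (inherits(x, "transformed_matrix")) x$provenance else character()
}

#' Counts-per-million normalization
#'
#' Scales every cell (column) so its entries sum to one million. Cells with
#' zero total counts cannot be normalized and raise an error naming the
#' offending barcode.
#'
#' @param counts genes x cells count matrix.
#' @return a `transformed_matrix` with provenance `"cpm"`.
#' @export
#' @examples
#' m <- matrix(c(1L, 1L, 2L, 6L), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' cpm_normalize(m)$values
cpm_normalize <- function(counts) {
  validate_counts(counts)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[which(totals == 0)]
    abort(sprintf("cannot CPM-normalize cells with zero total counts: %s%s",
                  paste(head(bad, 3), collapse = ", "),
                  if (length(bad) > 3) sprintf(" (and %d more)", length(bad) - 3)
                  else ""),
          class = "ddg_parameter_error")
  }
  scale <- 1e6 / totals
  if (is(counts, "sparseMatrix")) {
    # scale entries in place so sparse and dense inputs round identically
    scaled <- as(as(counts, "CsparseMatrix"), "generalMatrix")
    scaled <- as(scaled, "dMatrix")
    scaled@x <- scaled@x * rep.int(scale, diff(scaled@p))
  } else {
    scaled <- t(t(as.matrix(counts)) * scale)
  }
  new_transformed_matrix(scaled, "cpm")
}

#' Elementwise log(1 + x) transform
#'
#' Natural-log "log+1" transform of a non-negative expression matrix;
#' zeros map to zeros, so sparsity is preserved.
#'
#' @param x a `transformed_matrix` (typically from [cpm_normalize()]) or a
#'   non-negative matrix.
#' @return a `transformed_matrix` with `"log1p"` appended to the provenance.
#' @export
log1p_transform <- function(x) {
  v <- transform_values(x)
  vals <- if (is(v, "sparseMatrix")) v@x else as.vector(as.matrix(v))
  if (length(vals) && (anyNA(vals) || any(vals < 0))) {
    abort("log1p transform requires non-negative entries",
          class = "ddg_parameter_error")
  }
  if (is(v, "sparseMatrix")) {
    out <- as(as(v, "CsparseMatrix"), "generalMatrix")
    out@x <- log1p(out@x)
  } else {
    out <- log1p(as.matrix(v))
  }
  new_transformed_matrix(out, c(transform_provenance(x), "log1p"))
}
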