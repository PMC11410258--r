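#' Validate a UMI count matrix
#'
#' Checks that `counts` is a genes-by-cells matrix of non-negative integer
#' values with unique gene and cell identifiers in its dimnames. Both base
#' matrices and sparse [Matrix::Matrix()] classes are accepted; all package
#' functions use this single internal convention (rows = genes, columns =
#' cells, 10x style).
#'
#' @param counts matrix or sparse Matrix of UMI counts (genes x cells).
#' @param arg name used in error messages.
#' @return `counts`, invisibly, if valid.
#' @export
validate_counts <- function(counts, arg = "counts") {
  if (!(is.matrix(counts) || is(counts, "Matrix"))) {
    abort(sprintf("`%s` must be a matrix or sparse Matrix", arg),
          class = "ddg_format_error")
  }
  vals <- if (is(counts, "sparseMatrix")) counts@x else as.vector(as.matrix(counts))
  if (length(vals) && (anyNA(vals) || any(vals < 0))) {
    abort(sprintf("`%s` contains negative or missing entries", arg),
          class = "ddg_format_error")
  }
  if (length(vals) && any(vals != floor(vals))) {
    abort(sprintf("`%s` contains non-integer entries", arg),
          class = "ddg_format_error")
  }
  gid <- rownames(counts)
  cid <- colnames(counts)
  if (is.null(gid) || is.null(cid)) {
    abort(sprintf("`%s` must carry gene ids (rownames) and cell ids (colnames)", arg),
          class = "ddg_format_error")
  }
  if (anyDuplicated(gid)) {
    abort("duplicated gene ids", class = "ddg_format_error")
  }
  if (anyDuplicated(cid)) {
    abort("duplicated cell ids", class = "ddg_format_error")
  }
  invisible(counts)
}

read_id_file <- function(path, what) {
  if (!file.exists(path)) {
    abort(sprintf("%s file not found: %s", what, path), class = "ddg_format_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  # first whitespace-delimited token per line; extra 10x columns ignored
  vapply(strsplit(lines, "[ \t]+"), `[[`, character(1), 1L)
}

#' Read a MatrixMarket count matrix with gene and barcode annotations
#'
#' Reads a 10x-style triplet: a MatrixMarket coordinate file plus plain-text
#' gene-id and cell-barcode files (first token per line is the id; extra
#' columns are ignored). Rows are genes and columns are cells.
#'
#' @param matrix_path path to the `.mtx` coordinate file.
#' @param genes_path path to the gene-id file (one gene per line).
#' @param barcodes_path path to the cell-barcode file (one cell per line).
#' @return sparse dgCMatrix of counts with gene/cell dimnames.
#' @export
read_mtx <- function(matrix_path, genes_path, barcodes_path) {
  if (!file.exists(matrix_path)) {
    abort(sprintf("matrix file not found: %s", matrix_path),
          class = "ddg_format_error")
  }
  m <- tryCatch(Matrix::readMM(matrix_path), error = function(e) {
    abort(sprintf("failed to parse MatrixMarket file %s: %s",
                  matrix_path, conditionMessage(e)),
          class = "ddg_format_error")
  })
  genes <- read_id_file(genes_path, "gene")
  cells <- read_id_file(barcodes_path, "barcode")
  if (length(genes) != nrow(m)) {
    abort(sprintf("gene file has %d ids but matrix has %d rows",
                  length(genes), nrow(m)),
          class = "ddg_format_error")
  }
  if (length(cells) != ncol(m)) {
    abort(sprintf("barcode file has %d ids but matrix has %d columns",
                  length(cells), ncol(m)),
          class = "ddg_format_error")
  }
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  dimnames(m) <- list(genes, cells)
  validate_counts(m)
  m
}

#' Write a count matrix as MatrixMarket plus annotation files
#'
#' Inverse of [read_mtx()]: writes the coordinate file (1-based indices, the
#' MatrixMarket standard) and one id per line for genes and barcodes.
#'
#' @param counts genes x cells count matrix with dimnames.
#' @inheritParams read_mtx
#' @return invisibly, `matrix_path`.
#' @export
write_mtx <- function(counts, matrix_path, genes_path, barcodes_path) {
  validate_counts(counts)
  m <- as(as(as(counts, "CsparseMatrix"), "generalMatrix"), "dMatrix")
  atomic_write(matrix_path, function(tmp) invisible(Matrix::writeMM(m, tmp)))
  atomic_write(genes_path, function(tmp) writeLines(rownames(counts), tmp))
  atomic_write(barcodes_path, function(tmp) writeLines(colnames(counts), tmp))
  invisible(matrix_path)
}

#' Read a dense delimited count matrix
#'
#' Reads a CSV/TSV table with a header row and an id column, and returns the
#' counts in the package's genes-by-cells orientation regardless of how the
#' file is laid out.
#'
#' @param path path to the delimited file; the separator (comma or tab) is
#'   detected from the header line.
#' @param orientation `"genes_by_cells"` if rows are genes (the default) or
#'   `"cells_by_genes"` if rows are cells.
#' @return sparse dgCMatrix of counts (genes x cells).
#' @export
read_dense <- function(path, orientation = c("genes_by_cells", "cells_by_genes")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "ddg_format_error")
  }
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE, row.names = 1L,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    abort(sprintf("non-numeric entries in %s", path), class = "ddg_format_error")
  }
  if (orientation == "cells_by_genes") m <- t(m)
  m <- Matrix::Matrix(m, sparse = TRUE)
  m <- as(as(m, "CsparseMatrix"), "generalMatrix")
  validate_counts(m)
  m
}

#' Read per-cell labels
#'
#' Reads a two-column TSV (cell barcode, label). A `cell_id<TAB>label` header
#' line is tolerated and skipped.
#'
#' @param path path to the TSV file.
#' @return tibble with columns `cell_id` and `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("label file not found: %s", path), class = "ddg_format_error")
  }
  df <- read.delim(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("cell_id", "label"), colClasses = "character")
  if (nrow(df) && identical(unname(unlist(df[1, ])), c("cell_id", "label"))) {
    df <- df[-1, , drop = FALSE]
  }
  tibble(cell_id = df$cell_id, label = df$label)
}

#' Write per-cell labels
#'
#' @param labels tibble/data frame with columns `cell_id` and `label`.
#' @param path output path (TSV, no header).
#' @return invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(all(c("cell_id", "label") %in% names(labels)))
  atomic_write(path, function(tmp) {
    write.table(labels[, c("cell_id", "label")], tmp, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  })
  invisible(path)
}

ddg_table_file_columns <- c("gene_id", "mean", "n_cells", "expected_cells",
                            "p_value", "q_value", "significant")

#' Write a DDG result table to TSV
#'
#' Writes the table produced by [select_ddgs()] with columns `gene_id`,
#' `mean`, `n_cells`, `expected_cells`, `p_value`, `q_value`, `significant`,
#' in the input gene order. Numeric values keep full double precision (15
#' significant digits).
#'
#' @param table a `ddg_table` (or compatible data frame).
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_ddg_table <- function(table, path) {
  out <- data.frame(
    gene_id = table$gene_id,
    mean = format(table$mean_count, digits = 15, trim = TRUE, scientific = FALSE),
    n_cells = table$n_cells_expressing,
    expected_cells = format(table$expected_cells, digits = 15, trim = TRUE,
                            scientific = FALSE),
    p_value = format(table$p_value, digits = 15, trim = TRUE),
    q_value = format(table$q_value, digits = 15, trim = TRUE),
    significant = table$significant,
    stringsAsFactors = FALSE
  )
  atomic_write(path, function(tmp) {
    write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
  })
  invisible(path)
}

#' Read back a DDG result table written by [write_ddg_table()]
#'
#' @param path TSV path.
#' @return tibble with the on-disk columns.
#' @export
read_ddg_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "ddg_format_error")
  }
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!identical(names(df), ddg_table_file_columns)) {
    abort(sprintf("unexpected columns in %s", path), class = "ddg_format_error")
  }
  as_tibble(df)
}

#' Read a one-gene-per-line feature set file
#'
#' @param path path to a text file with one gene id per line.
#' @return character vector of gene ids.
#' @export
read_feature_set <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("feature file not found: %s", path), class = "ddg_format_error")
  }
  ids <- readLines(path)
  ids[nzchar(trimws(ids))]
}

# write via a temp file in the same directory, then rename: readers never see
# a partially written file
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort(sprintf("output directory does not exist: %s", dir),
          class = "ddg_io_error")
  }
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    abort(sprintf("could not write %s", path), class = "ddg_io_error")
  }
  ok <- TRUE
  invisible(path)
}
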