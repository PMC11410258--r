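#' Simulate a Gaussian-mixture cell-type dataset
#'
#' Generates ground-truth molecule counts for a population made of discrete
#' cell types. Each cell type has its own block of marker genes: in cells of
#' the matching type a marker's molecule count is drawn from
#' `Normal(high_mean, high_sd)`, everywhere else (and for all non-marker
#' genes) from `Normal(low_mean, low_sd)`. Draws are rounded to the nearest
#' integer (half away from zero) and clamped at zero. With the defaults this
#' reproduces the validation setting of 3 types x 3000 cells, 1000 genes and
#' 900 markers with high counts ~ round(Normal(35, 2)) and background
#' ~ round(Normal(15, 1)).
#'
#' If `capture_p` is given, an observed matrix is also produced by putting
#' every molecule through an independent Bernoulli capture trial with that
#' probability (see [binomial_downsample()]).
#'
#' @param n_types number of cell types (default 3).
#' @param cells_per_type cells simulated per type (default 3000).
#' @param n_genes total number of genes (default 1000).
#' @param markers_per_type marker genes per type (default 300);
#'   `n_types * markers_per_type` must not exceed `n_genes`.
#' @param high_mean,high_sd Normal parameters for a marker in its own type
#'   (defaults 35 and 2, molecule counts per cell).
#' @param low_mean,low_sd Normal parameters for the background state
#'   (defaults 15 and 1).
#' @param capture_p optional per-molecule capture probability in `(0, 1]`;
#'   when given, the returned `observed` matrix is the captured data.
#' @param seed integer RNG seed; required so simulations are reproducible.
#' @return an object of class `gmm_sim`: a list with `truth` (genes x cells
#'   integer matrix of molecule counts), `observed` (captured counts, or
#'   `NULL`), `cell_labels` (tibble `cell_id`, `label`) and `marker_map`
#'   (tibble `gene_id`, `cell_type`, with `"none"` for non-markers).
#' @export
#' @examples
#' sim <- simulate_gmm(cells_per_type = 50, n_genes = 40, markers_per_type = 10,
#'                     capture_p = 0.05, seed = 42)
#' dim(sim$truth)
#' table(sim$marker_map$cell_type)
simulate_gmm <- function(n_types = 3, cells_per_type = 3000, n_genes = 1000,
                         markers_per_type = 300, high_mean = 35, high_sd = 2,
                         low_mean = 15, low_sd = 1, capture_p = NULL, seed) {
  if (missing(seed)) {
    abort("`seed` is required", class = "ddg_parameter_error")
  }
  if (n_types < 1 || cells_per_type < 1 || n_genes < 1 || markers_per_type < 0) {
    abort("simulator sizes must be positive (markers_per_type may be 0)",
          class = "ddg_parameter_error")
  }
  if (n_types * markers_per_type > n_genes) {
    abort("n_types * markers_per_type exceeds n_genes",
          class = "ddg_parameter_error")
  }
  if (!is.null(capture_p) &&
      (length(capture_p) != 1L || is.na(capture_p) ||
       capture_p <= 0 || capture_p > 1)) {
    abort("`capture_p` must be a single value in (0, 1]",
          class = "ddg_parameter_error")
  }
  n_cells <- n_types * cells_per_type
  gene_ids <- sprintf("gene%0*d", nchar(n_genes), seq_len(n_genes))
  type_names <- sprintf("type%d", seq_len(n_types))
  labels <- rep(type_names, each = cells_per_type)
  cell_ids <- sprintf("cell%0*d_%s", nchar(n_cells), seq_len(n_cells), labels)

  marker_type <- rep("none", n_genes)
  if (markers_per_type > 0) {
    marker_type[seq_len(n_types * markers_per_type)] <-
      rep(type_names, each = markers_per_type)
  }

  out <- with_seed(seed, {
    truth <- matrix(0L, n_genes, n_cells)
    for (t in seq_len(n_types)) {
      cols <- ((t - 1) * cells_per_type + 1):(t * cells_per_type)
      block <- round_half_away(rnorm(n_genes * cells_per_type, low_mean, low_sd))
      block <- matrix(pmax(block, 0), n_genes, cells_per_type)
      if (markers_per_type > 0) {
        rows <- ((t - 1) * markers_per_type + 1):(t * markers_per_type)
        hi <- round_half_away(rnorm(markers_per_type * cells_per_type,
                                    high_mean, high_sd))
        block[rows, ] <- matrix(pmax(hi, 0), markers_per_type, cells_per_type)
      }
      truth[, cols] <- block
    }
    storage.mode(truth) <- "integer"
    observed <- NULL
    if (!is.null(capture_p)) {
      observed <- matrix(rbinom(length(truth), truth, capture_p),
                         n_genes, n_cells)
      storage.mode(observed) <- "integer"
    }
    list(truth = truth, observed = observed)
  })
  dimnames(out$truth) <- list(gene_ids, cell_ids)
  if (!is.null(out$observed)) dimnames(out$observed) <- list(gene_ids, cell_ids)

  structure(
    list(truth = out$truth,
         observed = out$observed,
         cell_labels = tibble(cell_id = cell_ids, label = labels),
         marker_map = tibble(gene_id = gene_ids, cell_type = marker_type)),
    class = "gmm_sim")
}

#' @export
print.gmm_sim <- function(x, ...) {
  cat(sprintf(
    "# GMM simulation: %d genes x %d cells, %d marker genes, %s observed matrix\n",
    nrow(x$truth), ncol(x$truth), sum(x$marker_map$cell_type != "none"),
    if (is.null(x$observed)) "no" else "with"))
  invisible(x)
}

#' Ground-truth marker gene ids of a simulation
#'
#' @param sim a `gmm_sim` from [simulate_gmm()].
#' @return character vector of all marker gene ids (the truth feature set).
#' @export
marker_genes <- function(sim) {
  stopifnot(inherits(sim, "gmm_sim"))
  sim$marker_map$gene_id[sim$marker_map$cell_type != "none"]
}

#' Down-sample counts by per-molecule Bernoulli capture
#'
#' Replaces every entry n by a draw from `Binomial(n, p)` - distributionally
#' identical to putting each of the n molecules through an independent
#' Bernoulli trial with success probability p, but vectorized. Shape,
#' dimnames and matrix class (sparse or dense) are preserved.
#'
#' @param counts genes x cells count matrix.
#' @param p retention/capture probability in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return down-sampled count matrix of the same shape and class.
#' @export
#' @examples
#' m <- matrix(c(10L, 0L, 5L, 2L), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' binomial_downsample(m, 0.5, seed = 1)
binomial_downsample <- function(counts, p, seed) {
  validate_counts(counts)
  if (missing(seed)) {
    abort("`seed` is required", class = "ddg_parameter_error")
  }
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort("`p` must be a single value in [0, 1]", class = "ddg_parameter_error")
  }
  with_seed(seed, {
    if (is(counts, "sparseMatrix")) {
      out <- as(as(counts, "CsparseMatrix"), "generalMatrix")
      out@x <- as.double(rbinom(length(out@x), as.integer(out@x), p))
      Matrix::drop0(out)
    } else {
      out <- matrix(rbinom(length(counts), as.integer(counts), p),
                    nrow(counts), ncol(counts), dimnames = dimnames(counts))
      storage.mode(out) <- "integer"
      out
    }
  })
}

#' Simulate counts under the technical-noise null model
#'
#' Every cell starts with exactly the same number of molecules
#' \eqn{M_i = \mathrm{round}(\mu_i / p_c)} of gene i (molecules are
#' discrete, so the target mean `mean_grid` is converted to an integer
#' molecule count), and each molecule is captured independently with
#' probability `p_c`. The observed per-gene mean is then ~ `mean_grid` and
#' all variation across cells is purely technical - the regime in which the
#' DDG test should flag (almost) nothing.
#'
#' @param n_genes number of genes.
#' @param n_cells number of cells.
#' @param mean_grid target observed mean count per gene; recycled to
#'   `n_genes` values (each >= 0).
#' @param p_c capture probability in `(0, 1)`.
#' @param seed integer RNG seed.
#' @return sparse dgCMatrix of counts (genes x cells) with dimnames.
#' @export
simulate_null <- function(n_genes, n_cells, mean_grid, p_c, seed) {
  check_pc(p_c)
  if (missing(seed)) {
    abort("`seed` is required", class = "ddg_parameter_error")
  }
  if (n_genes < 1 || n_cells < 1) {
    abort("`n_genes` and `n_cells` must be >= 1", class = "ddg_parameter_error")
  }
  if (anyNA(mean_grid) || any(mean_grid < 0)) {
    abort("`mean_grid` must be non-negative", class = "ddg_parameter_error")
  }
  molecules <- round_half_away(rep_len(mean_grid, n_genes) / p_c)
  m <- with_seed(seed, {
    matrix(rbinom(n_genes * n_cells, rep(molecules, times = n_cells), p_c),
           n_genes, n_cells)
  })
  dimnames(m) <- list(sprintf("gene%0*d", nchar(n_genes), seq_len(n_genes)),
                      sprintf("cell%0*d", nchar(n_cells), seq_len(n_cells)))
  as(as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
}

# round half away from zero (so 0.5 -> 1), unlike base round()'s banker's
# rounding; negatives are clamped by callers
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# evaluate code with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (length(seed) != 1L || is.na(seed) || seed != floor(seed)) {
    abort("`seed` must be a single integer", class = "ddg_parameter_error")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}
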