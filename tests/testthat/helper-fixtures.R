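# shared fixtures, built in code at test time

# small random sparse count matrix with ids
random_counts <- function(n_genes = 50, n_cells = 100, lambda = 0.5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("c%03d", seq_len(n_cells)))
  methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
              "generalMatrix")
}

# the full-scale validation simulation, generated once per test run
.fixture_cache <- new.env(parent = emptyenv())

full_gmm <- function() {
  if (is.null(.fixture_cache$gmm)) {
    .fixture_cache$gmm <- simulate_gmm(seed = 20260101)
  }
  .fixture_cache$gmm
}

# reduced-size mixture for property tests that only need the structure
small_gmm <- function(seed = 11) {
  simulate_gmm(cells_per_type = 300, n_genes = 200, markers_per_type = 50,
               capture_p = 0.05, seed = seed)
}

# keeps the default 900-marker / 100-noise gene split but fewer cells, for
# neighbourhood-distortion checks that depend on the gene-space proportions
ajd_gmm <- function() {
  if (is.null(.fixture_cache$ajd_gmm)) {
    .fixture_cache$ajd_gmm <- simulate_gmm(cells_per_type = 300,
                                           capture_p = 0.05, seed = 27)
  }
  .fixture_cache$ajd_gmm
}

# brute-force dense k-NN: all-pairs distances + full sort (O(n^2) oracle)
brute_knn <- function(values, k) {
  v <- as.matrix(values)
  n <- ncol(v)
  d <- as.matrix(stats::dist(t(v)))
  nb <- t(vapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))
    ord[ord != i][seq_len(k)]
  }, integer(k)))
  if (k == 1L) nb <- matrix(as.integer(nb), n, 1) else nb
}

# independent lower-tail binomial oracle: cumulative summation of pmf terms
pmf_sum_oracle <- function(n_expr, n_total, p0) {
  sum(stats::dbinom(0:n_expr, n_total, 1 - p0))
}

# hand-written pair-counting ARI (closed form from the contingency table)
pair_count_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
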