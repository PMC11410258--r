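test_that("gene summaries match hand counts and a dense brute-force oracle", {
  m <- matrix(c(0L, 0L, 2L, 2L,
                0L, 0L, 0L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gZ"), sprintf("c%d", 1:4)))
  s <- summarize_genes(m)
  expect_equal(s$mean_count, c(1, 0))
  expect_equal(s$n_cells_expressing, c(2L, 0L))
  expect_equal(s$n_cells_total, c(4L, 4L))
  expect_true(is.na(s$cv[2]) && is.na(s$dispersion[2]))

  counts <- random_counts(n_genes = 50, n_cells = 100, seed = 2)
  s <- summarize_genes(counts)
  dense <- as.matrix(counts)
  for (i in seq_len(nrow(dense))) {
    x <- dense[i, ]
    expect_equal(s$mean_count[i], mean(x))
    expect_equal(s$variance[i], mean((x - mean(x))^2))
    expect_equal(s$n_cells_expressing[i], sum(x > 0))
  }
})

test_that("zero-count probability follows (1 - p_c)^(mean/p_c)", {
  expect_equal(zero_probability(0, 0.3), 1)
  expect_equal(zero_probability(0.05, 0.05), 0.95)  # one molecule, one trial
  expect_equal(zero_probability(1, 0.05), 0.95^20, tolerance = 1e-14)
  # log-space evaluation stays finite deep in the tail
  expect_gt(zero_probability(500, 0.05), 0)
  expect_error(zero_probability(1, 1.5), class = "ddg_parameter_error")
  expect_error(zero_probability(-1, 0.5), class = "ddg_parameter_error")
})

test_that("expected cells complements the zero probability and saturates", {
  expect_equal(expected_cells(0, 0.05, 100), 0)
  expect_equal(expected_cells(1, 0.05, 100), 100 * (1 - 0.95^20),
               tolerance = 1e-14)
  expect_equal(expected_cells(1e4, 0.05, 100), 100)
  for (mean in c(0, 0.01, 0.5, 1, 7, 40)) {
    expect_equal(expected_cells(mean, 0.05, 1000) / 1000 +
                   zero_probability(mean, 0.05), 1, tolerance = 1e-12)
  }
})

test_that("the deficit p-value is the exact binomial lower tail", {
  expect_equal(ddg_pvalue(10, 10, 0.5), 1)
  expect_equal(ddg_pvalue(2, 10, 0.5), 56 / 1024, tolerance = 1e-14)
  expect_equal(ddg_pvalue(1, 3, 0.25), 0.25^3 + 3 * 0.75 * 0.25^2,
               tolerance = 1e-14)
  # vectorized and monotone in the number of expressing cells
  p <- ddg_pvalue(0:50, 50, 0.4)
  expect_true(all(diff(p) >= 0))
  expect_equal(p[51], 1)
  # stable at very large cell numbers where naive summation would not be
  expect_gt(ddg_pvalue(993600L, 1000000L, 0.005), 0)
  expect_lt(ddg_pvalue(993600L, 1000000L, 0.005), 1e-50)
  expect_error(ddg_pvalue(5, 3, 0.5), class = "ddg_parameter_error")
  expect_error(ddg_pvalue(1, 3, 1.5), class = "ddg_parameter_error")
})

test_that("p-values agree with the pmf-summation oracle on a spot grid", {
  for (n_total in c(1, 7, 45, 160)) {
    for (p0 in c(0.01, 0.5, 0.99)) {
      for (n_expr in unique(c(0, 1, n_total %/% 2, n_total))) {
        expect_equal(ddg_pvalue(n_expr, n_total, p0),
                     pmf_sum_oracle(n_expr, n_total, p0),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_qvalues(0.03), 0.03)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(9)
  p <- runif(200)
  q <- bh_qvalues(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # monotone-consistent with the input ranks
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
  expect_error(bh_qvalues(c(0.1, NaN)), class = "ddg_parameter_error")
})

test_that("a matrix with identical counts in every cell yields no DDGs", {
  m <- matrix(rep(c(3L, 1L, 0L, 8L), each = 50), nrow = 4, byrow = TRUE,
              dimnames = list(sprintf("g%d", 1:4), sprintf("c%d", 1:50)))
  fit <- select_ddgs(m)
  expect_equal(sum(fit$significant), 0L)
  # every-cell-expressing genes sit at p = 1 by construction
  expect_equal(fit$p_value[fit$n_cells_expressing == 50], c(1, 1, 1))
})

test_that("zero-count genes are reported inert and excluded from BH", {
  counts <- as.matrix(random_counts(n_genes = 30, n_cells = 60, seed = 4))
  counts[5, ] <- 0L
  counts[17, ] <- 0L
  fit <- select_ddgs(counts)
  expect_equal(fit$p_value[c(5, 17)], c(1, 1))
  expect_equal(fit$q_value[c(5, 17)], c(1, 1))
  expect_false(any(fit$significant[c(5, 17)]))
  expect_equal(attr(fit, "n_tested"), 28L)
  # q-values of tested genes are unchanged by dropping the zero rows
  fit_sub <- select_ddgs(counts[-c(5, 17), ])
  expect_equal(fit$q_value[-c(5, 17)], fit_sub$q_value)
})

test_that("selection is invariant to cell order and equivariant to gene order", {
  counts <- as.matrix(random_counts(n_genes = 40, n_cells = 80, lambda = 1,
                                    seed = 6))
  fit <- select_ddgs(counts)
  set.seed(8)
  cell_perm <- sample(ncol(counts))
  fit_cells <- select_ddgs(counts[, cell_perm])
  expect_equal(tidy(fit), tidy(fit_cells))
  gene_perm <- sample(nrow(counts))
  fit_genes <- select_ddgs(counts[gene_perm, ])
  expect_equal(tidy(fit_genes), tidy(fit)[gene_perm, ])
})

test_that("under null data p-values are conservative (stochastically >= uniform)", {
  counts <- simulate_null(n_genes = 1000, n_cells = 2000,
                          mean_grid = 10^seq(log10(0.05), 1, length.out = 1000),
                          p_c = 0.05, seed = 31)
  fit <- select_ddgs(counts, p_c = 0.05, fdr = 0.01)
  p <- fit$p_value
  n <- length(p)
  for (t in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(p <= t), t + 4 * sqrt(t * (1 - t) / n))
  }
  # fraction flagged at FDR alpha stays at or below alpha within binomial error
  expect_lte(sum(fit$significant), qbinom(0.9999, n, 0.01))
})

test_that("tidy, glance, ddg_genes and autoplot expose the fit", {
  sim <- small_gmm()
  fit <- select_ddgs(sim$observed)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "ddg_table"))
  gl <- glance(fit)
  expect_equal(gl$n_significant, sum(fit$significant))
  expect_equal(gl$p_c, 0.05)
  expect_setequal(ddg_genes(fit), fit$gene_id[fit$significant])
  expect_s3_class(autoplot(fit), "ggplot")
  expect_output(print(fit), "DDG selection")
})

test_that("parameter bounds on p_c and fdr are enforced", {
  counts <- random_counts(n_genes = 5, n_cells = 10)
  expect_error(select_ddgs(counts, p_c = 0), class = "ddg_parameter_error")
  expect_error(select_ddgs(counts, p_c = 1), class = "ddg_parameter_error")
  expect_error(select_ddgs(counts, fdr = 0), class = "ddg_parameter_error")
  expect_error(select_ddgs(counts, fdr = 1), class = "ddg_parameter_error")
})
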