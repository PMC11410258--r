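#' Probability of observing zero counts under the binomial capture null
#'
#' Under the null model every cell carries the same number of molecules
#' \eqn{M_i} of gene i, and each molecule is captured independently with
#' probability `p_c`. The maximum-likelihood estimate of \eqn{M_i} from the
#' observed mean count \eqn{E(m_i)} is \eqn{E(m_i)/p_c}, so the chance that a
#' cell yields zero counts is
#' \deqn{p_0(i) = (1 - p_c)^{E(m_i)/p_c}.}
#' The (generally non-integer) exponent is used as is; the computation runs
#' in log space so very small probabilities do not underflow prematurely.
#'
#' @param mean_count observed mean UMI count per cell, \eqn{E(m_i)}
#'   (vectorized, each value >= 0).
#' @param p_c capture probability, a single value strictly between 0 and 1.
#' @return probability of a zero count, in `[0, 1]`, same length as
#'   `mean_count`.
#' @seealso [expected_cells()], [ddg_pvalue()], [select_ddgs()]
#' @export
#' @examples
#' zero_probability(0, 0.05)    # 1: nothing to capture
#' zero_probability(1, 0.05)    # 0.95^20
zero_probability <- function(mean_count, p_c) {
  check_pc(p_c)
  if (anyNA(mean_count) || any(mean_count < 0)) {
    abort("`mean_count` must be non-negative", class = "ddg_parameter_error")
  }
  exp((mean_count / p_c) * log1p(-p_c))
}

#' Expected number of cells expressing a gene under the null
#'
#' The complement of [zero_probability()] scaled by the number of cells:
#' \deqn{E(N_{c,i}) = N_T \left(1 - (1 - p_c)^{E(m_i)/p_c}\right).}
#' This is the characteristic mean-count versus cells-expressing curve that
#' all genes would follow if their variation were purely technical.
#'
#' @inheritParams zero_probability
#' @param n_cells_total total number of cells \eqn{N_T} (>= 1).
#' @return expected number of expressing cells, in `[0, n_cells_total]`.
#' @export
#' @examples
#' expected_cells(1, 0.05, 100)   # 100 * (1 - 0.95^20)
expected_cells <- function(mean_count, p_c, n_cells_total) {
  check_pc(p_c)
  if (length(n_cells_total) != 1L || is.na(n_cells_total) || n_cells_total < 1) {
    abort("`n_cells_total` must be a single integer >= 1",
          class = "ddg_parameter_error")
  }
  n_cells_total * (1 - zero_probability(mean_count, p_c))
}

#' Exact one-sided p-value for a deficit of expressing cells
#'
#' Under the null, whether each of the \eqn{N_T} cells expresses the gene is
#' an independent Bernoulli trial with success probability \eqn{1 - p_0}, so
#' the number of expressing cells is binomial. The p-value is the exact
#' lower-tail probability of observing the seen number of expressing cells
#' or fewer:
#' \deqn{p = \sum_{N=0}^{N_{c,i}} \binom{N_T}{N} (1-p_0)^N p_0^{N_T - N}.}
#' The tail is evaluated through the regularized incomplete beta function
#' (via [stats::pbinom()]), which is numerically stable up to millions of
#' cells, rather than by naive summation.
#'
#' @param n_cells_expressing observed number of cells with at least one
#'   count, \eqn{N_{c,i}} (vectorized).
#' @param n_cells_total total number of cells \eqn{N_T}.
#' @param p0 per-cell probability of zero counts, from [zero_probability()]
#'   (vectorized, in `[0, 1]`).
#' @return one-sided p-values in `[0, 1]`.
#' @export
#' @examples
#' ddg_pvalue(2, 10, 0.5)   # 56/1024
ddg_pvalue <- function(n_cells_expressing, n_cells_total, p0) {
  if (length(n_cells_total) != 1L || is.na(n_cells_total) || n_cells_total < 0) {
    abort("`n_cells_total` must be a single non-negative integer",
          class = "ddg_parameter_error")
  }
  if (anyNA(n_cells_expressing) || any(n_cells_expressing < 0) ||
      any(n_cells_expressing > n_cells_total)) {
    abort("`n_cells_expressing` must lie in [0, n_cells_total]",
          class = "ddg_parameter_error")
  }
  if (anyNA(p0) || any(p0 < 0) || any(p0 > 1)) {
    abort("`p0` must lie in [0, 1]", class = "ddg_parameter_error")
  }
  pbinom(n_cells_expressing, n_cells_total, 1 - p0)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up adjustment: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} n / j}, clipped at 1 and returned in
#' the input order. Thin wrapper over [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`; NA/NaN is an error.
#' @return q-values in input order.
#' @export
bh_qvalues <- function(p_values) {
  if (anyNA(p_values)) {
    abort("p-values contain NA/NaN", class = "ddg_parameter_error")
  }
  if (any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]", class = "ddg_parameter_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Per-gene summary statistics of a count matrix
#'
#' Computes, for every gene in input order: the mean UMI count over all
#' cells (zeros included), the population variance (divisor \eqn{N_T}),
#' dispersion (variance/mean) and coefficient of variation (sd/mean, both
#' `NA` for all-zero genes), the number of expressing cells and the total
#' cell count.
#'
#' @param counts genes x cells count matrix (see [validate_counts()]).
#' @return tibble with one row per gene: `gene_id`, `mean_count`, `variance`,
#'   `dispersion`, `cv`, `n_cells_expressing`, `n_cells_total`.
#' @export
summarize_genes <- function(counts) {
  validate_counts(counts)
  n_total <- ncol(counts)
  if (n_total == 0L) {
    abort("count matrix has zero cells", class = "ddg_parameter_error")
  }
  row_sum <- unname(Matrix::rowSums(counts))
  row_sq <- unname(Matrix::rowSums(counts * counts))
  mean_count <- row_sum / n_total
  variance <- pmax(row_sq / n_total - mean_count^2, 0)
  n_expr <- as.integer(unname(Matrix::rowSums(counts > 0)))
  dispersion <- ifelse(mean_count > 0, variance / mean_count, NA_real_)
  cv <- ifelse(mean_count > 0, sqrt(variance) / mean_count, NA_real_)
  tibble(
    gene_id = rownames(counts),
    mean_count = mean_count,
    variance = variance,
    dispersion = dispersion,
    cv = cv,
    n_cells_expressing = n_expr,
    n_cells_total = n_total
  )
}

#' Select differentially distributed genes (DDGs)
#'
#' Runs the full null-model pipeline: per-gene summaries, zero-count
#' probability \eqn{p_0}, expected number of expressing cells, exact
#' one-sided binomial p-value for a deficit of expressing cells, and
#' Benjamini-Hochberg correction at the chosen FDR. Genes observed in
#' significantly fewer cells than the null predicts are flagged as DDGs.
#'
#' Genes with zero total counts carry no information: they are reported with
#' `p_value = q_value = 1`, `significant = FALSE`, and are excluded from the
#' BH denominator so they do not deflate the q-values of tested genes.
#'
#' @param counts genes x cells UMI count matrix.
#' @param p_c assumed per-molecule capture probability (default 0.05;
#'   droplet protocols are typically in the 5-10\% range).
#' @param fdr false discovery rate for the BH step (default 0.01).
#' @return a `ddg_table`: a tibble with one row per gene in input order,
#'   columns `gene_id`, `mean_count`, `variance`, `dispersion`, `cv`,
#'   `n_cells_expressing`, `n_cells_total`, `expected_cells`, `p_value`,
#'   `q_value`, `significant`, plus attributes `p_c`, `fdr` and `n_tested`.
#'   Works with [tidy()], [glance()], [autoplot()] and [ddg_genes()].
#' @export
#' @examples
#' sim <- simulate_gmm(cells_per_type = 100, n_genes = 60, markers_per_type = 15,
#'                     capture_p = 0.05, seed = 1)
#' fit <- select_ddgs(sim$observed, p_c = 0.05, fdr = 0.01)
#' glance(fit)
select_ddgs <- function(counts, p_c = 0.05, fdr = 0.01) {
  check_pc(p_c)
  if (length(fdr) != 1L || is.na(fdr) || fdr <= 0 || fdr >= 1) {
    abort("`fdr` must be a single value in (0, 1)", class = "ddg_parameter_error")
  }
  summary <- summarize_genes(counts)
  n_total <- summary$n_cells_total[1]
  p0 <- zero_probability(summary$mean_count, p_c)
  expected <- n_total * (1 - p0)
  p_value <- ddg_pvalue(summary$n_cells_expressing, n_total, p0)
  tested <- summary$mean_count > 0
  q_value <- rep(1, nrow(summary))
  p_value[!tested] <- 1
  q_value[tested] <- bh_qvalues(p_value[tested])
  significant <- tested & q_value <= fdr
  out <- dplyr::mutate(summary,
                       expected_cells = expected,
                       p_value = p_value,
                       q_value = q_value,
                       significant = significant)
  new_ddg_table(out, p_c = p_c, fdr = fdr, n_tested = sum(tested))
}

new_ddg_table <- function(tbl, p_c, fdr, n_tested) {
  structure(tbl,
            class = c("ddg_table", class(tibble())),
            p_c = p_c, fdr = fdr, n_tested = n_tested)
}

#' Gene ids of the significant DDGs
#'
#' @param x a `ddg_table` from [select_ddgs()].
#' @return character vector of significant gene ids (a feature set).
#' @export
ddg_genes <- function(x) {
  stopifnot(inherits(x, "ddg_table"))
  x$gene_id[x$significant]
}

#' @export
print.ddg_table <- function(x, ...) {
  cat(sprintf(
    "# DDG selection: %d/%d genes significant (p_c = %g, FDR = %g, %d tested)\n",
    sum(x$significant), nrow(x), attr(x, "p_c"), attr(x, "fdr"),
    attr(x, "n_tested")))
  NextMethod()
}

#' @rdname select_ddgs
#' @param x a `ddg_table`.
#' @param ... unused.
#' @export
tidy.ddg_table <- function(x, ...) {
  as_tibble(unclass_ddg(x))
}

#' @rdname select_ddgs
#' @export
glance.ddg_table <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_tested = attr(x, "n_tested"),
    n_significant = sum(x$significant),
    fraction_significant = sum(x$significant) / nrow(x),
    p_c = attr(x, "p_c"),
    fdr = attr(x, "fdr"),
    n_cells_total = x$n_cells_total[1]
  )
}

#' Plot the mean-count versus cells-expressing curve
#'
#' Scatter of observed mean count against the number of expressing cells,
#' one point per gene, coloured by DDG significance, with the null-model
#' expectation \eqn{E(N_{c,i})} drawn as a curve. Genes falling below the
#' curve are expressed in fewer cells than technical noise predicts.
#'
#' @param object a `ddg_table` from [select_ddgs()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ddg_table <- function(object, ...) {
  p_c <- attr(object, "p_c")
  n_total <- object$n_cells_total[1]
  grid <- tibble(
    mean_count = exp(seq(log(max(min(object$mean_count[object$mean_count > 0],
                                     na.rm = TRUE), 1e-4)),
                         log(max(object$mean_count) + 1), length.out = 300))
  )
  grid$expected <- expected_cells(grid$mean_count, p_c, n_total)
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_count,
                                   y = .data$n_cells_expressing)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        size = 0.6, alpha = 0.7) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$mean_count, y = .data$expected),
                       linewidth = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 name = "DDG") +
    ggplot2::labs(x = "mean UMI count per cell",
                  y = "cells expressing",
                  title = sprintf("Binomial capture null (p_c = %g)", p_c))
}

unclass_ddg <- function(x) {
  attr(x, "p_c") <- NULL
  attr(x, "fdr") <- NULL
  attr(x, "n_tested") <- NULL
  class(x) <- class(tibble())
  x
}

check_pc <- function(p_c) {
  if (length(p_c) != 1L || is.na(p_c) || p_c <= 0 || p_c >= 1) {
    abort("`p_c` must be a single value strictly between 0 and 1",
          class = "ddg_parameter_error")
  }
  invisible(p_c)
}
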