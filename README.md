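# ddgenes

Feature selection for droplet single-cell RNA-seq from a binomial model of
mRNA capture.

## The problem

A droplet experiment observes only a small fraction of each cell's mRNA:
every molecule is captured with some probability p<sub>c</sub> (typically
5–10%), so most zeros in a UMI matrix are sampling artifacts, not biology.
The dominant feature-selection heuristic — highly variable genes (HVGs)
ranked by excess dispersion — has no model of that sampling process and
cannot say which genes vary for biological reasons. `ddgenes` implements a
statistically grounded alternative for analysts choosing feature genes
before clustering or trajectory analysis.

## The model

If every cell carried the same number of molecules
M<sub>i</sub> = E(m<sub>i</sub>)/p<sub>c</sub> of gene i, the probability
that a cell shows zero counts would be

> p<sub>0</sub>(i) = (1 − p<sub>c</sub>)<sup>E(m<sub>i</sub>)/p<sub>c</sub></sup>

and the number of cells expressing the gene would be
Binomial(N<sub>T</sub>, 1 − p<sub>0</sub>). The exact lower tail of that
binomial is a one-sided p-value for the gene being expressed in *fewer*
cells than technical noise predicts. After Benjamini–Hochberg correction
(default FDR 1%), the significant genes are the **differentially
distributed genes (DDGs)** — genes whose on/off pattern across cells
cannot be technical, with the number of features determined by the test
itself rather than an arbitrary cutoff.

The package also ships the validation machinery around the model: a
Gaussian-mixture ground-truth simulator with per-molecule binomial
down-sampling, the CPM/log1p transforms and binned-dispersion HVG baseline,
and evaluation metrics (exact k-NN average Jaccard distance, set overlap,
marker recovery, Wilcoxon DE reference sets, adjusted Rand index).

## Worked example

```r
library(ddgenes)

# ground-truth world: 3 cell types x 1000 cells, 500 genes, 450 markers,
# observed through a 5% capture process
sim <- simulate_gmm(cells_per_type = 1000, n_genes = 500,
                    markers_per_type = 150, capture_p = 0.05, seed = 7)

fit <- select_ddgs(sim$observed, p_c = 0.05, fdr = 0.01)
glance(fit)
#> # A tibble: 1 × 7
#>   n_genes n_tested n_significant fraction_significant   p_c   fdr n_cells_total
#> 1     500      500           448                0.896  0.05  0.01          3000

recovery_fraction(ddg_genes(fit), marker_genes(sim))
#> [1] 0.9955556
recovery_fraction(select_hvgs(sim$observed, n_top = 450), marker_genes(sim))
#> [1] 0.8933333
```

The DDG selector recovers 99.6% of the 450 true marker genes at this size
(at the full 9000-cell scale it recovers all of them), while the HVG
baseline, asked for the same number of genes, finds 89.3%. The first rows
of the fit show the machinery: observed mean, cells expressing, the
null-model expectation, and the exact tail p-value —

```r
tidy(fit)[1:2, c("gene_id", "mean_count", "n_cells_expressing",
                 "expected_cells", "p_value", "q_value")]
#>   gene_id mean_count n_cells_expressing expected_cells   p_value   q_value
#> 1 gene001       1.13               1975          2062. 0.000375  0.000468
#> 2 gene002       1.08               1908          2013. 0.0000265 0.0000526
```

`autoplot(fit)` draws every gene against the expected-cells curve, DDGs
highlighted. Neighbourhood distortion of a feature set is scored with
`average_jaccard_distance(knn_sets(m, 20), knn_sets(m[features, ], 20))`
(0 = neighbourhoods preserved, 1 = destroyed).

A command-line interface over the same functions lives at `inst/cli/ddg`
(subcommands `select`, `hvg`, `simulate`, `ajd`, `compare-sets`,
`wilcoxon`; see `?ddg_cli`).

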