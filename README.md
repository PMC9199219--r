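# scaddecon

Two-group bulk expression deconvolution with a SCAD-derivative-weighted
coupling penalty, and cell-type-specific differential expression by
jackknife z-tests.

## What it solves

Bulk RNA expression is a mixture of cell-type-specific profiles:
`Y = W H + ε`, with `Y` (genes × samples) observed, `W` (genes × cell
types) the per-cell-type expression, and `H` (cell types × samples)
non-negative mixing proportions whose columns sum to 1. Comparing two
groups of bulk samples — disease vs control, mutant vs wild type —
raises a confounded question: did the composition change, or did the
cell types themselves change expression? Assuming `W1 = W2` pushes all
signal into proportions; estimating `W1`, `W2` independently lets
estimation noise show up as spurious differential expression.

scaddecon estimates `W1, H1, W2, H2` simultaneously by minimizing

    1/2 ||Y1 − W1 H1||²_F + 1/2 ||Y2 − W2 H2||²_F
        + λ/2 Σ_{j,g} E_{jg} (W1 − W2)²_{gj}

over non-negative matrices. The weights `E` come from the derivative of
the SCAD (smoothly clipped absolute deviation) penalty evaluated on the
squared entry-wise differences of a short "warm-up" alternating-NNLS
fit: entries whose independent estimates already agree (squared
difference ≤ ζ, default 4) are held together with weight 1; entries
that differ strongly (squared difference ≥ aζ, a = 3.7) are left
completely free. The weighted W update is solved exactly, gene by
gene, as a stacked non-negative least-squares system. Entry-wise
standard errors of `W1 − W2` come from a leave-one-out jackknife
(`se = (n0−1)/√n0 · sd` over `n0 = min(n1, n2)` full reruns), feeding
two-sided normal z-tests for cell-type-specific differentially
expressed genes.

The package also ships the matching synthetic-data generator
(log-normal profiles, spiked differential entries, Dirichlet
proportions, additive Gaussian noise), a signature-matrix builder,
evaluation metrics (Kullback–Leibler divergence and RMSE for
proportions; TPR/FPR/PPV for differential calls), broom-style
`tidy()`/`glance()` methods, ggplot2 plots, and a command-line
interface.

## Worked example

```r
library(scaddecon)

truth <- simulate_dataset(simulation_config(m = 500, k = 4,
                                            n_per_group = 12, seed = 1))
sig    <- build_signature(truth$W1, truth$W2)   # top 5% most discriminating genes
params <- scaddecon_params(seed = 1)            # a = 3.7, zeta = 4, lambda = 1

fit <- scaddecon(truth$Y1, truth$Y2, signature = sig, params = params)
fit
#> Coupled two-group deconvolution fit
#>   500 genes, 4 cell types; 12 + 12 samples
#>   2 main-loop iteration(s); objective 65622.2 -> 65055.2
#>   coupling lambda = 1, zeta = 4, a = 3.7; free entries (E = 0): 74.6%

jk  <- jackknife_se(truth$Y1, truth$Y2, signature = sig, params = params)
deg <- deg_test(fit$W1, fit$W2, jk, alpha = 0.01)
deg[order(deg$p)[1:3], ]
#> # A tibble: 3 × 8
#>   gene    cell_type     diff    se      z     p direction degenerate
#>   <chr>   <chr>        <dbl> <dbl>  <dbl> <dbl> <chr>     <lgl>
#> 1 gene_18 celltype_1  25300.  31.8   796.     0 up        FALSE
#> 2 gene_39 celltype_1 -40390.  25.2 -1600.     0 down      FALSE
#> 3 gene_83 celltype_1 102148.  10.8  9436.     0 up        FALSE

met <- evaluate_metrics(fit$H1, truth$H1, deg = deg, de_mask = truth$de_mask)
met[c("kl", "rmse", "ppv", "sensitivity", "specificity")]
#> $kl          6.68e-13
#> $rmse        2.42e-07
#> $ppv         0.719
#> $sensitivity 0.87
#> $specificity 0.982
```

Reading the numbers: the fitted proportions are essentially exact
(mean per-sample KL divergence from the truth ~1e-13, RMSE ~2e-7 —
under the default generator the noise is tiny relative to the
expression scale); at `alpha = 0.01`, 87% of the truly spiked
(gene, cell type) entries are recovered with the correct direction,
72% of all calls are correct, and 98% of non-differential entries are
left uncalled. A gene's row in the table gives the estimated group
difference of its cell-type-specific expression, the jackknife SE, the
z-score, and the direction ("up" = higher in group 1).

The same pipeline runs from the shell (the launcher installs to
`inst/scripts/scaddecon`):

```sh
scaddecon simulate --m 500 --k 4 --n-per-group 12 --seed 1 --out-dir sim/
scaddecon deg --y1 sim/Y1.tsv --y2 sim/Y2.tsv --signature sim/signature.tsv \
          --seed 1 --out-dir out/
scaddecon evaluate --h-est out/H1.tsv --h-true sim/H1.tsv \
          --deg out/deg_table.tsv --mask sim/de_mask.tsv --out metrics.json
```

All matrix I/O is tab- or comma-delimited text with row identifiers in
the first column; every command is byte-reproducible given `--seed`.

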