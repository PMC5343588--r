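# vpnorm — variation-preserving between-sample normalization

Between-sample normalization of gene expression matrices (log2 scale,
genes × samples) **without the lack-of-variation assumption**. Median and
Quantile scaling — and the size-factor methods used for RNA-seq — implicitly
assume that most genes do not change between conditions; when differential
expression is extensive and unbalanced (mostly up, or mostly down), they
absorb real biology into the normalization factors, shrinking true changes
and breaking false-discovery-rate control downstream.

`vpnorm` implements two condition-decomposition methods that avoid this:

* **MedianCD** — median scaling within each condition's replicates, then a
  median-based between-condition step restricted to *no-variation genes*;
* **SVCD** — the same structure with **Standard-Vector normalization** in
  each step: each gene's replicate vector is standardized onto the unit
  (s−2)-sphere in the zero-sum hyperplane, where exchangeability of correctly
  normalized samples forces the mean standard vector to zero; the offset
  estimate iterates `offsets += scale · mean standard vector` to that fixed
  point, with convergence judged against the estimator's own statistical
  error. The construction is distribution-free.

The normalization problem decomposes exactly: per-sample offsets = a
zero-sum within-condition part (estimable from *all* genes, since replicates
share no differential expression) plus a per-condition between part. Only
the between step can be confounded by differential expression, so it is
restricted to genes with no evidence of variation: per-gene one-way ANOVA
p-values across conditions are scanned with a one-sided Kolmogorov–Smirnov
uniformity test (α = 0.001), and the largest subset consistent with
uniformity is used — no prior fraction of null genes is assumed.

The package also ships the supporting apparatus of the accompanying
simulation study: a synthetic-data generator with exact truth bookkeeping
(per-treatment DEG fractions log-uniform in [0.9%, 90%], a dataset-wide 10%
never-DE reserve, unbalanced over/under-expression classes, injected
per-sample offsets), differential-expression calling (two-sample t-tests +
Benjamini–Hochberg per comparison), and TPR/FDR/balance evaluation against
the generator truth.

## Worked example

```r
library(vpnorm)

# a synthetic study: 4,000 genes, 12 treatments each with its own control,
# triplicates, unbalanced differential expression (DEG fractions drawn
# log-uniformly in [10%, 90%]), injected per-sample offsets
spec <- generator_spec(g = 4000, treatments = 12, controls = 12, seed = 11,
                       deg_fraction_range = c(0.10, 0.90))
sim <- simulate_expression(spec)

fit <- normalize_cd(sim$expression, sim$design, method = "svcd")
fit
#> svcd normalization: 72 samples, 24 conditions
#>   total offsets: sd 0.1681, range [-0.3579, 0.3465] (log2)
#>   no-variation genes: 284
#>   iterations: 29, converged: TRUE

# recovered factors track the injected ones; Median normalization's do not,
# because the unbalanced differential expression drags the medians
truth <- sim$truth$true_offsets - mean(sim$truth$true_offsets)
cor(fit$total, truth)
#> [1] 0.9286989
cor(median_normalize(sim$expression, design = sim$design)$total, truth)
#> [1] 0.3569219

# differential expression for one treatment, FDR controlled at 5%
normalized <- apply_offsets(sim$expression, fit)
tbl <- ttest_treatment(normalized, sim$design, "T12", fdr = 0.05)
ev <- evaluate_calls(tbl, sim$truth, "T12")
round(c(tpr = ev$tpr, fdr = ev$fdr, balance = ev$balance), 3)
#>     tpr     fdr balance 
#>   0.021   0.020  -0.100
```

(Statistical power with triplicates and plain t-tests is deliberately
modest; the point of the comparison is that the realized FDR stays at the
nominal bound while the normalization preserves the injected variation.)

The printed summary reads: per-sample offsets on the log2 scale (sd and
range of the estimated normalization factors), the size of the detected
no-variation gene set used in the final between-condition step, and whether
the between-condition loop met its convergence criterion. `fit$diagnostics`
holds the per-iteration trace (offset sd, numerical vs statistical error,
set size); `fit$pvalues` the final per-gene ANOVA p-values.

Baselines for comparison: `median_normalize()`, `quantile_normalize()`;
`benchmark_suite()` runs the full simulate → normalize → call → score loop
over methods and replicates, and `variation_curve()` reproduces the
between-condition-variation diagnostic (estimator error decays as k^(−1/2)
on random gene subsets; genuine variation plateaus under p-ranked
selection).

A thin command-line wrapper is included at
`inst/scripts/normalize_cli.R`:

```sh
Rscript inst/scripts/normalize_cli.R --data expr.tsv --design design.tsv \
    --method svcd --out run1
```

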