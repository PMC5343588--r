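---
title: "Variation-preserving normalization by condition decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variation-preserving normalization by condition decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Between-sample normalization of expression data estimates, for each sample
$i$, an additive log2 offset $a_i$ (a multiplicative factor on the linear
scale) so that expression levels become comparable across samples. The
methods in everyday use — Median and Quantile scaling for arrays, and the
size-factor methods of the RNA-seq world — all rest on a *lack-of-variation
assumption*: most genes are taken to be non-differentially expressed, so
that matching medians (or whole distributions) across samples is harmless.
When differential expression is extensive and *unbalanced* — many more
genes up than down, or vice versa — that assumption is false, and these
methods absorb real biological variation into the offsets. The damage is
twofold: true changes are shrunk (lost power) and spurious changes are
created in unaffected genes (uncontrolled false discovery rate).

`vpnorm` implements normalization that makes no such assumption, in two
variants, MedianCD and SVCD, both built on the same *condition
decomposition*.

## Condition decomposition

With $g$ genes, $c$ experimental conditions, and $n_k$ replicate samples in
condition $k$, write the observed log2 expression of gene $j$ in condition
$k$ as $y_j^{(k)} = x_j^{(k)} + a^{(k)}$, with $x$ the true levels and
$a^{(k)}$ the per-sample offsets of that condition. Splitting every vector
into its mean and residual (zero-sum) parts decomposes the problem
*exactly* into

* one **within-condition** normalization per condition, acting on the
  residual parts of the replicates, and
* one **between-condition** normalization acting on the $g \times c$ matrix
  of condition means.

Two properties make the split powerful. First, within a condition no gene
is differentially expressed by definition — replicates are exchangeable —
so the within steps may use *all* genes. Second, only the between step is
exposed to differential expression, and it can be restricted to genes that
show no evidence of variation across conditions ("no-variation genes"),
detected from the data themselves. The within steps also supply honest
within-condition variance estimates, which is why at least two samples per
condition are required. The residual grand-mean degree of freedom is fixed
by a global convention: total offsets are centered to mean zero over all
samples, preserving the global expression level.

## Standard-vector normalization

For one set of $s$ exchangeable samples, each gene's values form an
$s$-vector; after subtracting the gene mean and scaling to unit norm, these
*standard vectors* live on the unit $(s-2)$-sphere inside the zero-sum
hyperplane. Exchangeability implies their distribution is
permutation-invariant with zero expectation — for *any* noise
distribution; no Gaussianity is assumed. Residual offsets tilt the cloud,
so the mean standard vector estimates the (scaled) offset direction.

The iteration in `sv_normalize()` is

1. standardize the current iterate, excluding zero-residual genes and
   trimming the 1% most extreme residual variances (0.5% per tail by
   default; the trim is recomputed every step on the current iterate);
2. update the offsets by `scale * mean standard vector`, where `scale` is
   the median residual norm of the retained genes — a robust map from
   sphere displacements back to log2 units;
3. stop when the *numerical error* (per-sample RMS of the update,
   $\|u\|/\sqrt{s}$) falls below `tol_hard` (1%) of the *statistical
   error*, or below `tol_soft` (10%) of it for `soft_run` (10) consecutive
   steps.

The statistical error (`sv_statistical_error()`) is the norm of the
standard error of the mean standard vector, mapped to log2 units:
$\mathrm{scale} \cdot \|\widehat{\sigma}_c\| / \sqrt{g'}$ under the
assumption of independent genes. It is the method's noise floor: iterating
below it buys nothing, which is exactly what the stopping rule encodes.
The update vanishes exactly at the fixed point (mean standard vector zero),
is first-order exact for small offsets, and contracts fastest for
spherically symmetric noise. With $s = 2$ the sphere degenerates to two
points and the fixed point is reached when the median log-difference
between the two samples is zero — a robust variant of the global (constant)
Loess correction, whose classical form zeroes the *mean* log-difference;
the two coincide for symmetric noise.

Numerical choices worth recording: trimming ranks are tie-broken by gene
id, so results are independent of row order; there is no randomness
anywhere in the normalizer; non-convergence within `max_steps` (100) is
flagged, never masked; fewer than 10 retained genes is an error, since the
mean standard vector would be meaningless.

## Detecting no-variation genes

`anova_pvalues()` computes a classic one-way fixed-effects F-test per gene
across all conditions of the (current) normalized data. Under correct
normalization the null genes' p-values are uniform; differential expression
piles p-values near zero. `select_novariation()` scans candidate thresholds
$p_0$ over the observed p-values, largest candidate set first; the subset
$\{p \ge p_0\}$ is rescaled to $u = (p - p_0)/(1 - p_0)$ — uniform on
$[0,1]$ under the null for a left-truncated uniform — and tested with a
one-sided Kolmogorov–Smirnov statistic $D^+$, which is sensitive precisely
to an excess of small values (contamination). The largest subset not
rejected at $\alpha = 0.001$ wins. No prior fraction of null genes is
assumed anywhere; the single search over the p-value space replaces it.

Search schedule: an exact descending scan when there are at most 512
candidate thresholds, otherwise a 64-point coarse grid followed by an exact
local refinement between the last rejected and first accepted grid points.
The rejection boundary is monotone for all realistic contamination
patterns, which is what the refinement relies on. Ties in p are broken by
gene id, so selection is deterministic and order-independent. A floor of
100 genes is enforced (with a warning below 500): the between-step
estimation error decays as $1/\sqrt{g'}$, so sets much smaller than several
hundred genes normalize poorly. Inside the iterative loop of
`normalize_cd()` a failed search falls back to the least-rejected candidate
subset (`strict = FALSE`) — early iterations can be so contaminated by
still-uncorrected offsets that nothing passes, and aborting there would be
self-defeating; convergence is only ever declared on iterations whose
search genuinely passed.

## The full MedianCD / SVCD procedure

`normalize_cd()` chains the pieces:

1. within-normalize each condition with all genes (median scaling for
   MedianCD, standard vectors for SVCD);
2. iterate the between step: one normalization move on the current
   no-variation set (initially all genes), then re-run the ANOVA on the
   offset-adjusted sample-level data and re-select the set;
3. declare convergence — MedianCD when the relative change in the standard
   deviation of the between offsets is below 0.1%, or below 10% for 10
   consecutive steps; SVCD when the move's numerical error is below 1% of
   its statistical error, or below 10% of it for 10 consecutive steps —
   then run 10 further steps and intersect their no-variation sets;
4. re-run the between normalization to full convergence on the intersected
   set, compose within + between offsets, and center globally.

Two structural decisions deserve a note. The SVCD between loop takes *one*
standard-vector move per iteration rather than a fully converged inner run:
the set is re-identified after every move, and a full inner run would jump
to each successive set's own fixed point, leaving the step size dominated
by set-to-set jitter rather than true progress. And the MedianCD between
offset for a gene subset is the mean over each condition's samples of the
per-sample subset median of within-normalized data — under this composition
(and only under it) running MedianCD with *all* genes reproduces
conventional Median normalization exactly, as it should: the subset
restriction is then the *only* thing that distinguishes the methods. A
known-negative gene list can be supplied via `novariation_genes=`,
bypassing detection, for spike-in-style data where truth is external.

Degenerate corners: an empty intersection falls back to the last non-empty
set with a warning; a between-offset standard deviation of exactly zero is
immediate convergence; exceeding `max_outer_steps` (50) returns a result
flagged non-converged.

## The synthetic study

`generator_spec()` / `simulate_expression()` generate the study conditions
under which the claims are tested. Per gene, values are independent normals
whose mean and variance play the role of a real dataset's per-gene sample
moments taken across *all* samples of a multi-condition study. The
defaults: mean levels $\mathcal{N}(8, 2^2)$ log2; per-gene standard
deviations log-normal with median 0.9 and log-sd 0.35. The variance scale
matters and is deliberately large: across dozens of heterogeneous
conditions a strongly modulated transcriptome's total per-gene variance is
dominated by between-condition variation, and probes are assumed
signal-filtered, so very small variances are rare. Under the literal
effect rule this puts most injected fold changes in the 2–4-fold range.

Differential expression: each of the (default 42) treatments draws its DEG
fraction log-uniformly from [0.9%, 90%]; DEGs come from outside a reserved
10% never-DE set, and the reserve is *exact* — pool genes the random draws
missed are swapped in for multiply-covered genes, preserving every
treatment's DEG count. Treatments belong round-robin to three direction
classes with over-expression probabilities 0.9 / 0.1 / 0.5, giving the
unbalance spectrum the evaluation sweeps. The effect rule defaults to the
literal form — mean shift equal to twice the gene's *variance* — with
`effect_rule = "sd"` available since the literal rule is dimensionally odd
(its effect-to-noise ratio $2\sigma$ grows with the noise). Injected
per-sample offsets are drawn $\mathcal{N}(0, 0.2^2)$ log2 and centered, or
supplied explicitly. All randomness flows from one seed; identical spec and
seed give bit-identical output.

What the generator does *not* emulate: gene–gene correlation, count noise,
intensity-dependent (non-linear) distortions, batch structure, and missing
values. Passing tests therefore demonstrate correctness of the estimators
under clean additive-offset conditions, not robustness to every artifact of
real assays; the within-sample issues are explicitly upstream of this
package's scope.

## Evaluation

`ttest_treatment()` calls differential expression per treatment–control
pair with pooled-variance two-sample t-tests (Welch optional) and
Benjamini–Hochberg adjustment *within each comparison* (the bound is per
comparison, not global), calling at adjusted $p \le 0.05$ by default.
`evaluate_calls()` scores calls against generator truth: TPR (true
positives over treatment positives), realized FDR (false positives over
detected positives, zero when nothing is detected), the balance
$B = \mathrm{mean}(\pm 1)$ over detected DEGs, fold-change quartiles, and a
p-value-swept ROC, optionally restricted to a known-gene subset.
`benchmark_suite()` wires simulate → normalize → call → score across
scenarios, methods, and replicates; `variation_curve()` reproduces the
diagnostic that separates estimator error (random gene subsets decay as
$k^{-1/2}$) from genuine between-condition variation (p-ranked subsets
plateau, then collapse once variant genes enter).

Problem sizes used by the shipped tests and acceptance script — chosen as
representative desk-scale versions of the study design — are 5,000 genes ×
24 conditions (FDR control, 10 replicates), 10,000 genes × 51 conditions
(no-variation purity, 5 seeds), and 18,339 genes × 51 conditions (generator
bookkeeping). One property test deliberately departs from triplicates: the
FDR-inflation contrast between the baselines and the CD methods is read off
treatments with many positives and $|B| \ge 0.6$ using **five** replicates
per condition, because pooled t-tests at $df = 4$ call so few genes that
every method's realized FDR is counting noise; with $df = 8$ the calls are
numerous enough for the realized FDR to reflect normalization bias, which
is the property under test. (An empirical-Bayes moderated test would give
triplicates the same effective degrees of freedom, but plain t-tests are
this package's calling engine.)

## Known limitations

* The no-variation search needs several hundred genuinely stable genes;
  datasets where nearly everything varies leave the between step with a
  large, honestly reported error.
* Identifiability has a degenerate corner: if a large coherent gene set is
  differentially expressed in *every* treatment by a similar shift, it
  mimics a null set under a shifted normalization. Many conditions with
  varying DE fractions and directions (the intended use) break the
  degeneracy; tiny designs with uniformly extreme DE may not.
* Purity of the detected no-variation set degrades with the mass of
  *weak* DEGs (effects below the per-gene noise): such genes are
  statistically indistinguishable from nulls by any test, and under the
  literal effect rule their number is controlled by the low-variance tail
  of the gene-variance distribution.
* ANOVA and t-tests assume within-condition homoscedastic normal noise;
  the normalizers themselves are distribution-free, the *detector* is not.
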