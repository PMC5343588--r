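Package: vpnorm
Title: Variation-Preserving Between-Sample Normalization of Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Between-sample normalization of log2 gene expression matrices
    without the usual assumption that most genes are not differentially
    expressed. The normalization problem is decomposed exactly into
    per-condition within-normalizations plus one between-condition
    normalization of condition means (MedianCD and SVCD normalization).
    The between step uses only no-variation genes, identified by a
    one-sided Kolmogorov-Smirnov uniformity search on per-gene ANOVA
    p-values. Includes Standard-Vector normalization of exchangeable
    replicates on the unit hypersphere, conventional Median and Quantile
    baselines, a synthetic-data generator with unbalanced differential
    expression and known truth, and power/false-discovery-rate evaluation
    of differential expression calling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
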