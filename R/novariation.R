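#' Per-gene one-way ANOVA p-values across conditions
#'
#' Classic fixed-effects one-way F-test per gene, grouping samples by
#' experimental condition: under the null of no variation between condition
#' means (and after correct normalization), the p-values are uniform on
#' [0, 1]. Computed in closed form from the between- and within-group sums
#' of squares, with p from the F distribution on (c - 1, N - c) degrees of
#' freedom.
#'
#' Genes with zero between- and within-group variance carry no evidence of
#' variation and get p = 1.
#'
#' @param m Expression matrix (genes x samples), normalized (between-
#'   condition offsets applied) before testing.
#' @param design Design data frame; >= 2 conditions with >= 2 samples each.
#' @return Named numeric vector of p-values, one per gene.
#' @export
anova_pvalues <- function(m, design) {
    check_design(design, m)
    cond <- condition_of(design, m)
    conds <- unique(unname(cond))
    if (length(conds) < 2L)
        stop_vp("ANOVA needs at least two conditions")
    N <- ncol(m)
    c_ <- length(conds)
    grand <- rowMeans(m)
    ss_tot <- rowSums((m - grand)^2)
    ssb <- rep(0, nrow(m))
    for (k in conds) {
        cols <- which(cond == k)
        n_k <- length(cols)
        mk <- rowMeans(m[, cols, drop = FALSE])
        ssb <- ssb + n_k * (mk - grand)^2
    }
    ssw <- pmax(ss_tot - ssb, 0)
    f <- (ssb / (c_ - 1L)) / (ssw / (N - c_))
    p <- pf(f, c_ - 1L, N - c_, lower.tail = FALSE)
    degenerate <- ssw < 1e-12 & ssb < 1e-12
    p[degenerate] <- 1
    names(p) <- rownames(m)
    p
}

#' One-sided Kolmogorov-Smirnov uniformity test
#'
#' Goodness-of-fit test of values in [0, 1] against the uniform
#' distribution, one-sided in the direction D+ = sup(F_empirical -
#' F_uniform): sensitive to an excess of small values, which is how
#' differentially expressed genes contaminate a candidate set of
#' no-variation p-values.
#'
#' @param u Numeric vector in [0, 1], length >= 5.
#' @return List with `statistic` (D+) and `p.value`.
#' @export
ks_uniform_onesided <- function(u) {
    if (length(u) == 0L) stop_vp("empty input")
    if (length(u) < 5L) stop_vp("need at least 5 values")
    if (any(u < 0 | u > 1)) stop_vp("values must lie in [0, 1]")
    k <- suppressWarnings(ks.test(u, "punif", alternative = "greater"))
    list(statistic = unname(k$statistic), p.value = k$p.value)
}

#' Select no-variation genes from a p-value profile
#'
#' No-variation genes show no evidence of differential expression: the
#' p-values of a pure null subset are uniform above any truncation point.
#' The selector scans candidate thresholds p0 over the observed p-values,
#' largest candidate set first; each subset `{p >= p0}` is rescaled to
#' `u = (p - p0) / (1 - p0)` (uniform on [0, 1] under the null) and tested
#' with the one-sided KS test. The largest subset not rejected at `alpha`
#' is returned. No fraction of non-differentially expressed genes is
#' assumed; the single search over the p-value space replaces any such
#' prior.
#'
#' When the number of candidate thresholds is large the scan uses a coarse
#' grid followed by an exact local refinement between the last rejected and
#' first accepted grid points (the rejection boundary is monotone for all
#' practical contamination patterns).
#'
#' @param pvalues Named numeric vector of per-gene p-values in [0, 1].
#' @param alpha KS rejection level; default 0.001.
#' @param min_genes Smallest admissible set; below `500` selected genes a
#'   warning notes that normalization needs no-variation genes of the order
#'   of several hundreds. Default 100.
#' @param strict If `TRUE` (default), failing to find any admissible subset
#'   consistent with uniformity is an error. With `strict = FALSE` the
#'   candidate subset with the highest KS p-value is returned instead,
#'   flagged `passed = FALSE`; [normalize_cd()] uses this inside its
#'   between-condition loop, where early iterations can be contaminated by
#'   still-uncorrected offsets.
#' @return List with `gene_ids` (sorted), `threshold` (smallest p included),
#'   `ks_alpha`, `n`, and `passed`.
#' @export
select_novariation <- function(pvalues, alpha = 0.001, min_genes = 100L,
                               strict = TRUE) {
    if (is.null(names(pvalues)))
        stop_vp("pvalues must be named by gene id")
    if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
        stop_vp("p-values must lie in [0, 1]")
    # Deterministic order: decreasing p, ties broken by gene id.
    ord <- order(-pvalues, names(pvalues))
    p_sorted <- unname(pvalues[ord])
    ids_sorted <- names(pvalues)[ord]
    g <- length(p_sorted)
    if (g < min_genes)
        stop_vp("fewer than min_genes = ", min_genes, " p-values supplied")
    # Candidate thresholds: unique p-values whose set {p >= p0} has at least
    # min_genes members; index i means the set of the i largest p-values.
    sizes <- which(!duplicated(p_sorted, fromLast = TRUE))  # last index per value
    sizes <- sizes[sizes >= min_genes]
    if (length(sizes) == 0L)
        sizes <- g
    ks_p <- function(size) {
        p0 <- p_sorted[size]
        if (p0 >= 1) return(1)  # all ones: perfectly non-rejectable
        u <- (p_sorted[seq_len(size)] - p0) / (1 - p0)
        ks_uniform_onesided(u)$p.value
    }
    passes <- function(size) ks_p(size) >= alpha
    # sizes is increasing; scan from the largest set downward.
    sizes <- rev(sizes)
    found <- NA_integer_
    if (length(sizes) <= 512L) {
        for (size in sizes) {
            if (passes(size)) { found <- size; break }
        }
    } else {
        grid <- unique(round(seq(1L, length(sizes), length.out = 64L)))
        hit <- NA_integer_
        for (i in grid) {
            if (passes(sizes[i])) { hit <- i; break }
        }
        if (!is.na(hit)) {
            lo <- if (hit == grid[1L]) 1L else grid[max(which(grid < hit))] + 1L
            found <- sizes[hit]
            for (i in seq.int(lo, hit)) {  # exact refinement, larger sets first
                if (passes(sizes[i])) { found <- sizes[i]; break }
            }
        }
    }
    passed <- !is.na(found)
    if (!passed) {
        if (strict)
            stop_vp("no subset of >= ", min_genes, " genes is consistent ",
                    "with uniformity: too few no-variation genes for ",
                    "normalization (several hundreds are needed)")
        # Best-effort selection: the least-rejected candidate subset.
        probe <- if (length(sizes) <= 512L) sizes
                 else sizes[unique(round(seq(1L, length(sizes),
                                             length.out = 64L)))]
        scores <- vapply(probe, ks_p, numeric(1))
        found <- probe[which.max(scores)]
    }
    if (passed && found < 500L)
        warn_vp("only ", found, " no-variation genes selected; ",
                "normalization error grows below several hundreds")
    list(gene_ids = sort(ids_sorted[seq_len(found)]),
         threshold = p_sorted[found],
         ks_alpha = alpha,
         n = found,
         passed = passed)
}
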