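#' Two-sample t-tests of one treatment against its control
#'
#' Per gene, a two-sample Student t-test (pooled variance by default, Welch
#' with `var_equal = FALSE`) of the treatment samples against the control
#' samples on normalized log2 values, with Benjamini-Hochberg adjustment
#' within the comparison and calls at the stated FDR bound. The log2 fold
#' change is the treatment mean minus the control mean.
#'
#' Degenerate genes (zero pooled variance) get p = 1 when the mean
#' difference is also zero, and p = 0 (flagged) otherwise.
#'
#' @param m Normalized expression matrix (genes x samples).
#' @param design Design data frame.
#' @param treatment,control Condition ids; `control` defaults to the
#'   design's control for `treatment`.
#' @param fdr FDR bound for calls; default 0.05.
#' @param var_equal Pooled-variance Student t (default) or Welch.
#' @return A data frame of class `diffexp_table`: `gene_id`, `t`, `p`,
#'   `padj`, `lfc`, `call`, `degenerate`; attributes `treatment`, `control`,
#'   `fdr`.
#' @export
ttest_treatment <- function(m, design, treatment, control = NULL,
                            fdr = 0.05, var_equal = TRUE) {
    check_design(design, m)
    control <- control %||% unname(control_map(design)[treatment])
    if (is.null(control) || is.na(control))
        stop_vp("no control condition known for treatment ", treatment)
    sx <- design$sample_id[design$condition_id == treatment]
    sy <- design$sample_id[design$condition_id == control]
    if (length(sx) < 2L || length(sy) < 2L)
        stop_vp("both conditions need >= 2 replicates")
    x <- m[, sx, drop = FALSE]
    y <- m[, sy, drop = FALSE]
    n1 <- ncol(x); n2 <- ncol(y)
    m1 <- rowMeans(x); m2 <- rowMeans(y)
    v1 <- row_vars(x); v2 <- row_vars(y)
    lfc <- m1 - m2
    if (var_equal) {
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        se <- sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- rep(n1 + n2 - 2, length(se))
    } else {
        se <- sqrt(v1 / n1 + v2 / n2)
        df <- (v1 / n1 + v2 / n2)^2 /
            ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
    tt <- lfc / se
    p <- 2 * pt(-abs(tt), df)
    degenerate <- se == 0
    zero_diff <- degenerate & lfc == 0
    p[zero_diff] <- 1
    tt[zero_diff] <- 0
    p[degenerate & !zero_diff] <- 0
    padj <- p.adjust(p, method = "BH")
    out <- data.frame(gene_id = rownames(m), t = tt, p = p, padj = padj,
                      lfc = lfc, call = padj <= fdr,
                      degenerate = degenerate,
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "treatment") <- treatment
    attr(out, "control") <- control
    attr(out, "fdr") <- fdr
    class(out) <- c("diffexp_table", "data.frame")
    out
}

#' Balance of detected differential expression
#'
#' Mean of a +/-1 indicator over the detected DEGs: +1 per over-expressed,
#' -1 per under-expressed gene. B = 1 means all detected DEGs are
#' over-expressed; B = -0.2 corresponds, for example, to 60% of DEGs
#' under-expressed. Undefined (NA) when nothing is called.
#'
#' @param tbl A [ttest_treatment()] table.
#' @return Scalar in [-1, 1], or `NA` with no detected DEGs.
#' @export
balance_score <- function(tbl) {
    called <- tbl$call
    if (!any(called)) return(NA_real_)
    mean(sign(tbl$lfc[called]))
}

#' Evaluate differential-expression calls against generator truth
#'
#' Computes, for one treatment, the true positive rate (true positives over
#' treatment positives), the realized false discovery rate (false positives
#' over detected positives; 0 when nothing is detected), the balance B of
#' detected DEGs, quartiles of absolute fold change among detected DEGs,
#' and an ROC curve swept over the p-value thresholds. When `known_genes`
#' is given, detected and treatment positives/negatives are restricted to
#' that gene set (the spike-in style of evaluation).
#'
#' @param tbl A [ttest_treatment()] table.
#' @param truth A `synthetic_truth` from [simulate_expression()].
#' @param treatment Treatment condition id (defaults to the table's).
#' @param known_genes Optional gene id subset for restricted evaluation.
#' @return List with `tpr`, `fdr`, `balance`, `n_called`, `n_true_pos`,
#'   `n_false_pos`, `fc_quartiles`, and `roc` (data frame: threshold, tpr,
#'   fpr, n_tp, n_fp).
#' @export
evaluate_calls <- function(tbl, truth, treatment = NULL, known_genes = NULL) {
    stopifnot(inherits(truth, "synthetic_truth"))
    treatment <- treatment %||% attr(tbl, "treatment")
    if (!treatment %in% colnames(truth$de_indicator))
        stop_vp("truth does not cover treatment ", treatment)
    keep <- tbl$gene_id %in% rownames(truth$de_indicator)
    tbl <- tbl[keep, , drop = FALSE]
    if (!is.null(known_genes))
        tbl <- tbl[tbl$gene_id %in% known_genes, , drop = FALSE]
    is_pos <- truth$de_indicator[tbl$gene_id, treatment]
    called <- tbl$call
    n_tp <- sum(called & is_pos)
    n_fp <- sum(called & !is_pos)
    tpr <- if (sum(is_pos) == 0L) NA_real_ else n_tp / sum(is_pos)
    fdr <- if (sum(called) == 0L) 0 else n_fp / sum(called)
    fc_q <- if (any(called)) {
        quantile(abs(tbl$lfc[called]), c(0.25, 0.5, 0.75), names = FALSE)
    } else {
        rep(NA_real_, 3L)
    }
    thresholds <- sort(unique(tbl$p))
    roc <- do.call(rbind, lapply(thresholds, function(th) {
        pos <- tbl$p <= th
        data.frame(threshold = th,
                   tpr = if (sum(is_pos) == 0L) NA_real_
                         else sum(pos & is_pos) / sum(is_pos),
                   fpr = if (sum(!is_pos) == 0L) NA_real_
                         else sum(pos & !is_pos) / sum(!is_pos),
                   n_tp = sum(pos & is_pos), n_fp = sum(pos & !is_pos))
    }))
    list(tpr = tpr, fdr = fdr, balance = balance_score(tbl),
         n_called = sum(called), n_true_pos = n_tp, n_false_pos = n_fp,
         fc_quartiles = fc_q, roc = roc)
}

# Normalize a matrix with one of the four methods; returns the normalized
# matrix (quantile) or applies the estimated offsets.
normalize_by_method <- function(m, design, method, ...) {
    switch(method,
           median = apply_offsets(m, median_normalize(m, design = design)),
           quantile = quantile_normalize(m),
           mediancd = apply_offsets(m, normalize_cd(m, design,
                                                    method = "mediancd", ...)),
           svcd = apply_offsets(m, normalize_cd(m, design,
                                                method = "svcd", ...)),
           stop_vp("unknown method: ", method))
}

#' Simulation benchmark of normalization methods
#'
#' For each scenario x method x replicate: simulate a dataset, normalize,
#' call differential expression per treatment with t-tests + BH at the FDR
#' bound, and score against the generator truth. Returns one row per
#' treatment with the realized TPR, FDR, detected-DEG count and balance,
#' alongside the true balance and treatment-positive count - the raw
#' material for TPR/FDR-versus-balance and DEG-count summaries.
#'
#' @param scenarios A [generator_spec()] or list of them (named, optionally).
#' @param methods Character subset of `c("median", "quantile", "mediancd",
#'   "svcd")`.
#' @param reps Replicate datasets per scenario.
#' @param seed Base seed; replicate r of scenario i uses `seed + 1000 * (i -
#'   1) + r`.
#' @param fdr FDR bound for calls.
#' @param ... Passed to [normalize_cd()] for the CD methods.
#' @return Data frame with columns `scenario`, `method`, `rep`, `treatment`,
#'   `n_treatment_pos`, `balance_true`, `tpr`, `fdr`, `n_called`,
#'   `balance`.
#' @export
benchmark_suite <- function(scenarios, methods = c("median", "quantile",
                                                   "mediancd", "svcd"),
                            reps = 1L, seed = 1L, fdr = 0.05, ...) {
    if (inherits(scenarios, "generator_spec")) scenarios <- list(scenarios)
    if (is.null(names(scenarios)))
        names(scenarios) <- sprintf("scenario%02d", seq_along(scenarios))
    rows <- list()
    for (i in seq_along(scenarios)) {
        for (r in seq_len(reps)) {
            sim <- simulate_expression(scenarios[[i]],
                                       seed = seed + 1000L * (i - 1L) + r)
            for (method in methods) {
                norm <- normalize_by_method(sim$expression, sim$design,
                                            method, ...)
                for (tr in names(sim$truth$control_of)) {
                    tbl <- ttest_treatment(norm, sim$design, tr, fdr = fdr)
                    ev <- evaluate_calls(tbl, sim$truth, tr)
                    is_pos <- sim$truth$de_indicator[, tr]
                    b_true <- if (any(is_pos))
                        mean(sim$truth$direction[is_pos, tr]) else NA_real_
                    rows[[length(rows) + 1L]] <- data.frame(
                        scenario = names(scenarios)[i], method = method,
                        rep = r, treatment = tr,
                        n_treatment_pos = sum(is_pos),
                        balance_true = b_true,
                        tpr = ev$tpr, fdr = ev$fdr,
                        n_called = ev$n_called, balance = ev$balance,
                        stringsAsFactors = FALSE)
                }
            }
        }
    }
    do.call(rbind, rows)
}

#' Plot TPR and FDR against the balance of differential expression
#'
#' Quick base-graphics view of a [benchmark_suite()] result: one panel for
#' the true positive rate and one for the realized FDR, each against the
#' true balance B, colored by normalization method, with the FDR bound
#' marked.
#'
#' @param bench A [benchmark_suite()] data frame.
#' @param fdr_bound Reference line for the FDR panel; default 0.05.
#' @return `bench`, invisibly.
#' @export
plot_benchmark <- function(bench, fdr_bound = 0.05) {
    methods <- unique(bench$method)
    cols <- stats::setNames(seq_along(methods) + 1L, methods)
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
    for (what in c("tpr", "fdr")) {
        plot(bench$balance_true, bench[[what]], type = "n",
             xlab = "balance B of injected DE", ylab = toupper(what),
             ylim = c(0, 1))
        for (meth in methods) {
            sel <- bench$method == meth
            points(bench$balance_true[sel], bench[[what]][sel],
                   col = cols[meth], pch = 16)
        }
        if (what == "fdr") abline(h = fdr_bound, lty = 2)
        legend("topleft", legend = methods, col = cols, pch = 16, bty = "n")
    }
    invisible(bench)
}
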