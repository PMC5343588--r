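#' Configuration for condition-decomposition normalization
#'
#' Bundles the convergence and detection parameters of [normalize_cd()].
#' The defaults are the ones used for all reported normalizations: MedianCD
#' converges when the relative change in the standard deviation of the
#' between-condition normalization factors is below 0.1%, or below 10% for
#' 10 steps in a row; SVCD converges when the numerical error of the
#' between step is below 1% of its estimated statistical error, or below
#' 10% of it for 10 steps in a row. The no-variation set is then stabilized
#' by intersecting the sets found during 10 additional steps. A laxer soft
#' tolerance (e.g. 0.30) can be set for stubborn datasets.
#'
#' @param method `"svcd"` or `"mediancd"`.
#' @param ks_alpha KS rejection level for no-variation detection.
#' @param min_novariation Smallest admissible no-variation set.
#' @param tol_hard Hard convergence tolerance (0.001 for mediancd relative
#'   sd change; 0.01 for svcd numerical/statistical error ratio).
#' @param tol_soft Soft tolerance (default 0.10).
#' @param soft_run Consecutive soft steps required (default 10).
#' @param extra_steps Additional steps whose no-variation sets are
#'   intersected after convergence (default 10).
#' @param max_outer_steps Cap on between-condition iterations.
#' @param sv_trim,sv_tol_hard,sv_tol_soft,sv_soft_run,sv_max_steps
#'   Parameters of the inner [sv_normalize()] runs (svcd only).
#' @return A list of class `cd_config`.
#' @export
cd_config <- function(method = c("svcd", "mediancd"),
                      ks_alpha = 0.001, min_novariation = 100L,
                      tol_hard = NULL, tol_soft = 0.10, soft_run = 10L,
                      extra_steps = 10L, max_outer_steps = 50L,
                      sv_trim = 0.01, sv_tol_hard = 0.01,
                      sv_tol_soft = 0.10, sv_soft_run = 10L,
                      sv_max_steps = 100L) {
    method <- match.arg(method)
    tol_hard <- tol_hard %||% if (method == "mediancd") 0.001 else 0.01
    stopifnot(tol_hard > 0, tol_soft > 0, soft_run >= 1L, extra_steps >= 1L)
    structure(list(method = method, ks_alpha = ks_alpha,
                   min_novariation = as.integer(min_novariation),
                   tol_hard = tol_hard, tol_soft = tol_soft,
                   soft_run = as.integer(soft_run),
                   extra_steps = as.integer(extra_steps),
                   max_outer_steps = as.integer(max_outer_steps),
                   sv_trim = sv_trim, sv_tol_hard = sv_tol_hard,
                   sv_tol_soft = sv_tol_soft,
                   sv_soft_run = as.integer(sv_soft_run),
                   sv_max_steps = as.integer(sv_max_steps)),
              class = "cd_config")
}

#' MedianCD convergence criterion on the between-offset history
#'
#' Converged when the relative change of the standard deviation of the
#' normalization factors between consecutive steps is below `tol_hard`, or
#' below `tol_soft` for `soft_run` consecutive steps; a standard deviation
#' of exactly zero converges immediately (nothing left to normalize).
#'
#' @param sd_history Numeric vector: sd of the cumulative between-condition
#'   offsets at each step, oldest first.
#' @param tol_hard,tol_soft,soft_run Criterion parameters (defaults 0.001,
#'   0.10, 10).
#' @return Logical: has the criterion been met by the last step?
#' @export
mediancd_converged <- function(sd_history, tol_hard = 0.001,
                               tol_soft = 0.10, soft_run = 10L) {
    n <- length(sd_history)
    if (n >= 1L && sd_history[n] == 0) return(TRUE)
    if (n < 2L) return(FALSE)
    rel <- abs(diff(sd_history)) / sd_history[-n]
    rel[!is.finite(rel)] <- Inf
    if (rel[n - 1L] < tol_hard) return(TRUE)
    run <- 0L
    for (r in rel) run <- if (r < tol_soft) run + 1L else 0L
    run >= soft_run
}

# One between-condition normalization move restricted to a gene subset, with
# error estimates. For MedianCD the per-condition offset is the mean over the
# condition's samples of the per-sample subset median of the within-normalized
# data; this is the composition under which using all genes reproduces
# conventional Median normalization exactly (after within-normalization every
# sample's all-gene median is identically its condition's centering constant).
# A median move is idempotent, so one move completes the subset's
# normalization. For SVCD the move operates on the condition-mean matrix:
# `full = FALSE` (the iterative between loop, where the no-variation set is
# re-identified after every move) takes a single standard-vector step, whose
# numerical/statistical error pair drives the outer convergence criterion;
# `full = TRUE` (the final between normalization on the settled set) runs
# sv_normalize to convergence.
between_step <- function(mm, mw, cond, genes, cfg, full = TRUE) {
    sub <- mm[genes, , drop = FALSE]
    if (cfg$method == "mediancd") {
        sample_med <- apply(mw[genes, , drop = FALSE], 2L, median)
        delta <- tapply(sample_med, cond[names(sample_med)], mean)
        delta <- stats::setNames(as.numeric(delta), names(delta))[colnames(mm)]
        delta <- center(delta)
        list(delta = delta, numerical_error = NA_real_,
             statistical_error = NA_real_, converged = TRUE)
    } else if (!full) {
        sv <- sv_standardize(sub, trim = cfg$sv_trim)
        step <- sv_step(sv)
        list(delta = step$update,
             numerical_error = step$numerical_error,
             statistical_error = sv_statistical_error(sv),
             converged = TRUE)
    } else {
        fit <- sv_normalize(sub, trim = cfg$sv_trim,
                            tol_hard = cfg$sv_tol_hard,
                            tol_soft = cfg$sv_tol_soft,
                            soft_run = cfg$sv_soft_run,
                            max_steps = cfg$sv_max_steps)
        last <- fit$trace[nrow(fit$trace), ]
        c_ <- ncol(sub)
        list(delta = fit$offsets,
             numerical_error = sqrt(sum(fit$offsets^2) / c_),
             statistical_error = last$statistical_error,
             converged = fit$converged)
    }
}

#' MedianCD and SVCD normalization by condition decomposition
#'
#' Normalizes a complete log2 expression matrix without assuming that most
#' genes are non-differentially expressed. The procedure: (1) each
#' experimental condition's replicates are within-normalized using all genes
#' (median scaling for MedianCD, [sv_normalize()] for SVCD; within a
#' condition no gene is differentially expressed, so all genes are valid
#' there); (2) the per-gene condition means form the reduced
#' between-condition problem; (3) the between step iterates: normalize the
#' condition means restricted to the current no-variation set (initially all
#' genes), recompute per-gene ANOVA p-values on the offset-adjusted
#' sample-level data, and reselect no-variation genes, until the method's
#' convergence criterion holds; (4) the sets found during `extra_steps`
#' further iterations are intersected; (5) a final between-condition
#' normalization uses only the intersected set; (6) within- and
#' between-offsets are composed and globally centered.
#'
#' @param m Complete expression matrix (genes x samples), log2 scale; use
#'   [filter_complete()] first if values are missing.
#' @param design Design data frame (see [read_design()]).
#' @param method `"svcd"` or `"mediancd"` (ignored when `config` is given).
#' @param config A [cd_config()]; built from `method` and `...` otherwise.
#' @param novariation_genes Optional character vector of gene ids to use as
#'   the no-variation set, bypassing detection entirely (the "known
#'   negatives supplied as input" mode; with all genes, MedianCD reproduces
#'   conventional Median normalization exactly).
#' @param ... Passed to [cd_config()].
#' @return A [norm_result] with within/between/total offsets, the detected
#'   no-variation gene set, final per-gene ANOVA p-values, and per-iteration
#'   diagnostics.
#' @examples
#' spec <- generator_spec(g = 600, treatments = 4, controls = 2,
#'                        deg_fraction_range = c(0, 0), seed = 7)
#' sim <- simulate_expression(spec)
#' fit <- normalize_cd(sim$expression, sim$design, method = "mediancd",
#'                     min_novariation = 50)
#' fit
#' @export
normalize_cd <- function(m, design, method = c("svcd", "mediancd"),
                         config = NULL, novariation_genes = NULL, ...) {
    if (is.null(config)) config <- cd_config(match.arg(method), ...)
    stopifnot(inherits(config, "cd_config"))
    check_design(design, m)
    if (anyNA(m))
        stop_vp("matrix has missing values; apply filter_complete() first")
    cond <- condition_of(design, m)
    slices <- split_by_condition(m, design)
    c_ <- length(slices)
    if (c_ < 2L) stop_vp("need at least two conditions")

    ## (1) within-condition normalizations, all genes
    within_ok <- TRUE
    within <- unlist(lapply(slices, function(slice) {
        if (config$method == "mediancd") {
            center(apply(slice, 2L, median))
        } else {
            fit <- sv_normalize(slice, trim = config$sv_trim,
                                tol_hard = config$sv_tol_hard,
                                tol_soft = config$sv_tol_soft,
                                soft_run = config$sv_soft_run,
                                max_steps = config$sv_max_steps)
            if (!fit$converged) within_ok <<- FALSE
            fit$offsets
        }
    }), use.names = FALSE)
    names(within) <- unlist(lapply(slices, colnames), use.names = FALSE)
    within <- within[colnames(m)]
    mw <- sweep_offsets(m, within)

    ## (2) condition means of within-normalized data
    cm <- condition_means(mw, design)
    mm <- cm$means

    ## Supplied no-variation set: skip detection, go straight to the final
    ## between-condition normalization.
    if (!is.null(novariation_genes)) {
        missing <- setdiff(novariation_genes, rownames(m))
        if (length(missing) > 0L)
            stop_vp("unknown no-variation gene(s): ",
                    paste(head(missing, 5L), collapse = ", "))
        final <- between_step(mm, mw, cond, novariation_genes, config)
        madj <- sweep_offsets(mw, unname(final$delta[cond]))
        return(compose_offsets(within = within, between = final$delta,
                               condition_of = cond, method = config$method,
                               novariation = novariation_genes,
                               iterations = 0L,
                               converged = final$converged && within_ok,
                               pvalues = anova_pvalues(madj, design)))
    }

    ## (3) iterative between step with no-variation detection
    genes <- rownames(m)
    novar <- genes
    b <- stats::setNames(rep(0, c_), colnames(mm))
    sd_history <- numeric(0)
    diag_rows <- vector("list", config$max_outer_steps)
    converged_at <- NA_integer_
    sets_after <- list()
    steps_done <- 0L
    for (t in seq_len(config$max_outer_steps)) {
        steps_done <- t
        step <- between_step(sweep_offsets(mm, b),
                             sweep_offsets(mw, unname(b[cond])),
                             cond, novar, config, full = FALSE)
        b <- b + step$delta
        madj <- sweep_offsets(mw, unname(b[cond]))
        p <- anova_pvalues(madj, design)
        sel <- suppressWarnings(
            select_novariation(p, alpha = config$ks_alpha,
                               min_genes = config$min_novariation,
                               strict = FALSE))
        novar <- sel$gene_ids
        sd_history <- c(sd_history, sd(b))
        diag_rows[[t]] <- data.frame(step = t, sd_between = sd(b),
                                     numerical_error = step$numerical_error,
                                     statistical_error = step$statistical_error,
                                     n_novariation = length(novar),
                                     ks_passed = sel$passed)
        if (is.na(converged_at) && sel$passed) {
            done <- if (config$method == "mediancd") {
                mediancd_converged(sd_history, config$tol_hard,
                                   config$tol_soft, config$soft_run)
            } else {
                svcd_outer_converged(diag_rows, t, config)
            }
            if (done) converged_at <- t
        }
        if (!is.na(converged_at)) {
            sets_after <- c(sets_after, list(novar))
            if (length(sets_after) > config$extra_steps) break
        }
    }
    converged <- !is.na(converged_at)
    if (!converged)
        warn_vp("between-condition loop did not converge within ",
                config$max_outer_steps, " steps")

    ## (4) set convergence by intersection over the extra steps
    pool <- if (length(sets_after) > 1L) sets_after[-1L] else sets_after
    final_set <- if (length(pool) > 0L) Reduce(intersect, pool) else novar
    if (length(final_set) == 0L) {
        nonempty <- Filter(length, rev(sets_after))
        final_set <- if (length(nonempty) > 0L) nonempty[[1L]] else novar
        warn_vp("intersection of no-variation sets was empty; ",
                "falling back to the last non-empty set")
    }

    if (length(final_set) < 500L)
        warn_vp("only ", length(final_set), " no-variation genes in the ",
                "final set; normalization error grows below several hundreds")

    ## (5) final between-condition normalization on the detected set
    final <- between_step(mm, mw, cond, final_set, config)
    b_final <- final$delta

    ## (6) compose, center, and report diagnostics
    madj <- sweep_offsets(mw, unname(b_final[cond]))
    p_final <- anova_pvalues(madj, design)
    compose_offsets(within = within, between = b_final, condition_of = cond,
                    method = config$method,
                    novariation = final_set,
                    iterations = steps_done,
                    converged = converged && within_ok,
                    diagnostics = do.call(rbind, diag_rows[seq_len(steps_done)]),
                    pvalues = p_final)
}

# SVCD outer convergence: numerical error of the last between step below
# tol_hard x its statistical error, or below tol_soft x it for soft_run
# consecutive steps.
svcd_outer_converged <- function(diag_rows, t, cfg) {
    num <- vapply(diag_rows[seq_len(t)], function(d) d$numerical_error,
                  numeric(1))
    stat <- vapply(diag_rows[seq_len(t)], function(d) d$statistical_error,
                   numeric(1))
    ratio <- ifelse(stat > 0, num / stat, ifelse(num == 0, 0, Inf))
    if (ratio[t] <= cfg$tol_hard) return(TRUE)
    run <- 0L
    for (r in ratio) run <- if (r < cfg$tol_soft) run + 1L else 0L
    run >= cfg$soft_run
}

#' Between-condition variation as a function of the gene set used
#'
#' Diagnostic for variation preservation: redo the final between-condition
#' normalization with gene sets of increasing size, chosen either in
#' decreasing order of the no-variation p-values or at random, and measure
#' the surviving between-condition variation. The variation metric is the
#' standard deviation, across conditions, of the within-condition averages
#' of the per-sample grand means. With random selection on null data the
#' curve decays as k^(-1/2) (pure estimator error); with decreasing-p
#' selection on data with real between-condition variation it plateaus at
#' the true variation level until variant genes enter the set.
#'
#' @param m Expression matrix handed to [normalize_cd()].
#' @param design Design data frame.
#' @param fit A completed [normalize_cd()] result (supplies within offsets
#'   and p-values).
#' @param sizes Integer vector of gene-set sizes.
#' @param selection `"pvalue"` (top-k by decreasing p) or `"random"`.
#' @param seed Seed for random selection.
#' @return Data frame with columns `size`, `selection`, `variation`.
#' @export
variation_curve <- function(m, design, fit, sizes,
                            selection = c("pvalue", "random"), seed = NULL) {
    selection <- match.arg(selection)
    stopifnot(inherits(fit, "norm_result"))
    if (is.null(fit$pvalues))
        stop_vp("fit carries no p-values; run normalize_cd() first")
    if (any(sizes > nrow(m)))
        stop_vp("requested gene-set size exceeds the gene count")
    if (!is.null(seed)) set.seed(seed)
    cfg <- cd_config(fit$method)
    cond <- condition_of(design, m)
    mw <- sweep_offsets(m, fit$within)
    mm <- condition_means(mw, design)$means
    p <- fit$pvalues
    ranked <- names(p)[order(-p, names(p))]
    n_cond <- table(cond)[colnames(mm)]
    out <- lapply(sizes, function(k) {
        genes <- if (selection == "pvalue") ranked[seq_len(k)]
                 else sample(rownames(m), k)
        b <- between_step(mm, mw, cond, genes, cfg)$delta
        b <- b - sum(b * n_cond) / sum(n_cond)  # global centering
        normalized <- sweep_offsets(mw, unname(b[cond]))
        sample_means <- colMeans(normalized)
        cond_avgs <- tapply(sample_means, cond[names(sample_means)], mean)
        data.frame(size = k, selection = selection,
                   variation = sd(as.numeric(cond_avgs)))
    })
    do.call(rbind, out)
}
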