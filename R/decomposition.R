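#' Split an expression matrix by experimental condition
#'
#' The normalization problem decomposes exactly into one within-condition
#' normalization per condition plus one between-condition normalization of
#' the condition means. This returns the per-condition sample slices, in the
#' design's condition order.
#'
#' @param m Expression matrix (genes x samples).
#' @param design Design data frame (see [read_design()]).
#' @return Named list of matrices, one per condition; the union of the
#'   slices' columns is exactly the columns of `m`.
#' @export
split_by_condition <- function(m, design) {
    check_design(design, m)
    conds <- design_conditions(design)
    lapply(stats::setNames(conds, conds), function(k) {
        s <- design$sample_id[design$condition_id == k]
        m[, s, drop = FALSE]
    })
}

#' Condition means and within-condition variances
#'
#' Computes, per gene and condition, the unweighted mean of within-normalized
#' expression values together with the unbiased within-condition sample
#' variance. The means form the reduced between-condition normalization
#' problem; the variances feed the per-gene ANOVA used to detect no-variation
#' genes.
#'
#' @param m Expression matrix (genes x samples).
#' @param design Design data frame.
#' @param within Named numeric vector of within-condition offsets per sample
#'   (zero-sum inside each condition), or `NULL` for zero offsets.
#' @return List with `means` and `variances`, both genes x conditions
#'   matrices, plus `n` (named replicate counts).
#' @export
condition_means <- function(m, design, within = NULL) {
    check_design(design, m)
    if (!is.null(within)) m <- apply_offsets(m, within)
    slices <- split_by_condition(m, design)
    means <- vapply(slices, rowMeans, numeric(nrow(m)))
    vars <- vapply(slices, row_vars, numeric(nrow(m)))
    if (nrow(m) == 1L) {  # vapply drops to vector shape consistency
        means <- matrix(means, 1L, dimnames = list(rownames(m), names(slices)))
        vars <- matrix(vars, 1L, dimnames = list(rownames(m), names(slices)))
    }
    n <- vapply(slices, ncol, integer(1))
    list(means = means, variances = vars, n = n)
}

#' Compose within- and between-condition offsets
#'
#' Builds the complete per-sample normalization factors: each sample's total
#' offset is its within-condition offset plus its condition's
#' between-condition offset, globally centered so the mean total offset over
#' all samples is zero (the overall expression level is preserved).
#'
#' @param within Named numeric vector of per-sample within offsets.
#' @param between Named numeric vector of per-condition between offsets;
#'   every condition present in `condition_of` must appear.
#' @param condition_of Named character vector: sample id -> condition id.
#' @param method Label stored in the result.
#' @param ... Further fields passed to [norm_result()] (`novariation`,
#'   `iterations`, `converged`, `diagnostics`, `pvalues`).
#' @return A [norm_result] object.
#' @export
compose_offsets <- function(within, between, condition_of,
                            method = "cd", ...) {
    missing <- setdiff(unique(unname(condition_of)), names(between))
    if (length(missing) > 0L)
        stop_vp("no between-condition offset for condition(s): ",
                paste(missing, collapse = ", "))
    norm_result(method = method, condition_of = condition_of,
                within = within, between = between, ...)
}
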