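#' Standard vectors of a set of exchangeable samples
#'
#' Each gene's expression across the `s` samples is treated as an
#' s-dimensional vector; after mean subtraction and scaling to unit norm,
#' these standard vectors lie on the unit (s-2)-sphere inside the zero-sum
#' hyperplane. Under correct normalization of exchangeable samples their
#' distribution is permutation-invariant with zero expected value, which is
#' what Standard-Vector normalization exploits.
#'
#' Zero-residual (constant) genes are always excluded. Additionally, the
#' genes whose residual variance is most extreme are trimmed: a fraction
#' `trim / 2` from each tail by default, or `trim` from the upper tail only
#' with `side = "upper"`. Trimming ranks are tie-broken by gene id so the
#' result does not depend on input row order.
#'
#' @param values Numeric matrix, genes x samples (s >= 2), log2 scale.
#' @param trim Fraction of genes to trim by extreme residual variance, in
#'   [0, 0.5); default 0.01 (1%).
#' @param side `"both"` (default; `trim/2` per tail) or `"upper"`.
#' @return An object of class `sv_set`: list with `vectors` (retained genes
#'   x s, rows zero-sum and unit norm), `retained` and `trimmed` gene ids,
#'   and `scale`, the median residual norm of retained genes used to map
#'   sphere displacements to log2 offsets.
#' @export
sv_standardize <- function(values, trim = 0.01, side = c("both", "upper")) {
    side <- match.arg(side)
    stopifnot(is.matrix(values), ncol(values) >= 2L)
    if (trim < 0 || trim >= 0.5) stop_vp("trim must be in [0, 0.5)")
    g <- nrow(values)
    ids <- rownames(values) %||% as.character(seq_len(g))
    res <- values - rowMeans(values)
    norms2 <- rowSums(res^2)
    nonzero <- norms2 > 0
    # Trim by residual variance (monotone in residual norm), stable ties.
    idx <- which(nonzero)
    ord <- idx[order(norms2[idx], ids[idx])]
    n_avail <- length(ord)
    trimmed_idx <- integer(0)
    if (trim > 0 && n_avail > 0L) {
        if (side == "both") {
            n_lo <- floor(trim / 2 * n_avail)
            n_hi <- floor(trim / 2 * n_avail)
        } else {
            n_lo <- 0L
            n_hi <- floor(trim * n_avail)
        }
        if (n_lo > 0L) trimmed_idx <- c(trimmed_idx, ord[seq_len(n_lo)])
        if (n_hi > 0L)
            trimmed_idx <- c(trimmed_idx, ord[seq.int(n_avail - n_hi + 1L, n_avail)])
    }
    keep <- setdiff(ord, trimmed_idx)
    if (length(keep) < 10L)
        stop_vp("fewer than 10 genes retained; cannot estimate ",
                "standard-vector offsets")
    keep <- sort(keep)  # original gene order
    norms <- sqrt(norms2[keep])
    vectors <- res[keep, , drop = FALSE] / norms
    rownames(vectors) <- ids[keep]
    structure(list(vectors = vectors,
                   retained = ids[keep],
                   trimmed = sort(ids[c(which(!nonzero), trimmed_idx)]),
                   scale = median(norms)),
              class = "sv_set")
}

#' One Standard-Vector normalization step
#'
#' The offset update is the mean standard vector of the retained genes,
#' mapped to log2 units by the robust residual scale. At the method's fixed
#' point the mean standard vector vanishes, so the update is zero exactly
#' when the samples are already normalized.
#'
#' @param sv An `sv_set` from [sv_standardize()], built from the current
#'   iterate.
#' @return List with `update` (zero-sum numeric s-vector to add to the
#'   accumulated offsets) and `numerical_error`, the per-sample
#'   root-mean-square magnitude of the update.
#' @export
sv_step <- function(sv) {
    stopifnot(inherits(sv, "sv_set"))
    mean_sv <- colMeans(sv$vectors)
    update <- sv$scale * mean_sv
    s <- length(update)
    list(update = update,
         mean_vector_norm = sqrt(sum(mean_sv^2)),
         numerical_error = sqrt(sum(update^2) / s))
}

#' Statistical error of the Standard-Vector offset estimate
#'
#' Assuming independence between genes, the sampling error of the mean
#' standard vector has per-component standard error `sd_c / sqrt(g')`. The
#' returned value is the Euclidean norm of that error vector mapped to log2
#' offset units by the residual scale: `scale * ||component-wise sd|| /
#' sqrt(g')` - the standard error of the mean standard vector. It is the
#' noise floor against which the per-sample numerical error of each step is
#' compared for convergence.
#'
#' @param sv An `sv_set` from [sv_standardize()].
#' @return Non-negative scalar, log2 offset units.
#' @export
sv_statistical_error <- function(sv) {
    stopifnot(inherits(sv, "sv_set"))
    g <- nrow(sv$vectors)
    sd_c <- apply(sv$vectors, 2L, sd)
    sv$scale * sqrt(sum(sd_c^2)) / sqrt(g)
}

#' Standard-Vector normalization of one set of exchangeable samples
#'
#' Iteratively removes per-sample offsets from a set of samples that should
#' be exchangeable (e.g. the replicates of one experimental condition, or
#' condition means in the between-condition step). Each step re-standardizes
#' and re-trims the current iterate, adds `scale * mean standard vector` to
#' the accumulated offsets, and compares the numerical error (per-sample RMS
#' of the update) with the estimated statistical error of the estimator.
#' Convergence requires the numerical error to be below `tol_hard` times the
#' statistical error, or below `tol_soft` times it for `soft_run`
#' consecutive steps.
#'
#' With `s = 2` samples the sphere degenerates to two points and the
#' procedure reduces to a robust mean-difference correction (half the median
#' log-difference moved between the two samples), the degenerate global
#' Loess case.
#'
#' @param values Numeric matrix, genes x samples (s >= 2).
#' @param trim Trim fraction per step (see [sv_standardize()]).
#' @param tol_hard Hard tolerance, numerical/statistical error; default 0.01.
#' @param tol_soft Soft tolerance; default 0.10.
#' @param soft_run Consecutive steps required under the soft tolerance;
#'   default 10.
#' @param max_steps Iteration cap; exceeding it returns `converged = FALSE`.
#' @return List with `offsets` (named zero-sum numeric s-vector),
#'   `converged`, `iterations`, and `trace`, a data frame with one row per
#'   step (`step`, `mean_vector_norm`, `numerical_error`,
#'   `statistical_error`, `n_retained`).
#' @export
sv_normalize <- function(values, trim = 0.01, tol_hard = 0.01,
                         tol_soft = 0.10, soft_run = 10L, max_steps = 100L) {
    stopifnot(is.matrix(values), ncol(values) >= 2L)
    s <- ncol(values)
    offsets <- stats::setNames(rep(0, s), colnames(values))
    soft_count <- 0L
    converged <- FALSE
    trace <- vector("list", max_steps)
    t <- 0L
    while (t < max_steps) {
        t <- t + 1L
        current <- sweep_offsets(values, offsets)
        sv <- sv_standardize(current, trim = trim)
        step <- sv_step(sv)
        stat_err <- sv_statistical_error(sv)
        offsets <- offsets + step$update
        trace[[t]] <- data.frame(step = t,
                                 mean_vector_norm = step$mean_vector_norm,
                                 numerical_error = step$numerical_error,
                                 statistical_error = stat_err,
                                 n_retained = nrow(sv$vectors))
        if (step$numerical_error <= tol_hard * stat_err ||
            (stat_err == 0 && step$numerical_error == 0)) {
            converged <- TRUE
            break
        }
        if (step$numerical_error < tol_soft * stat_err) {
            soft_count <- soft_count + 1L
            if (soft_count >= soft_run) {
                converged <- TRUE
                break
            }
        } else {
            soft_count <- 0L
        }
    }
    offsets <- offsets - mean(offsets)  # numerical guard; updates are zero-sum
    list(offsets = offsets, converged = converged, iterations = t,
         trace = do.call(rbind, trace[seq_len(t)]))
}
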