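#' Conventional Median normalization
#'
#' Per sample, subtracts the median of the expression distribution and adds
#' back the overall median so that the global expression level is preserved;
#' equivalently, each sample's offset is its median minus the overall
#' median, with offsets then centered to zero mean. A gene subset may be
#' supplied, in which case both the sample medians and the overall median
#' are computed over that subset only (this is the median step used for the
#' between-condition normalization in MedianCD).
#'
#' @param m Expression matrix (genes x samples), log2 scale.
#' @param genes Optional character vector of gene ids (or logical/integer
#'   index) restricting the medians; default all genes.
#' @param design Optional design data frame; when given, sample-to-condition
#'   labels are stored in the result.
#' @return A [norm_result] object with zero between-condition offsets and
#'   `total` equal to the centered median offsets.
#' @export
median_normalize <- function(m, genes = NULL, design = NULL) {
    stopifnot(is.matrix(m))
    sub <- if (is.null(genes)) m else m[genes, , drop = FALSE]
    if (nrow(sub) == 0L) stop_vp("empty gene subset")
    offsets <- apply(sub, 2L, median) - median(sub)
    offsets <- center(offsets)
    cond <- if (is.null(design)) {
        stats::setNames(rep("all", ncol(m)), colnames(m))
    } else {
        check_design(design, m)
        condition_of(design, m)
    }
    norm_result(method = "median", condition_of = cond, within = offsets)
}

#' Quantile normalization
#'
#' Forces every sample's empirical distribution to equal the mean
#' order-statistic distribution, with tied ranks sharing the mean of their
#' would-be values, as implemented in the limma package. Unlike the other
#' methods this is not a per-sample shift, so a matrix is returned rather
#' than offsets.
#'
#' @param m Expression matrix (genes x samples), complete.
#' @return The quantile-normalized matrix, same dimnames as `m`.
#' @export
quantile_normalize <- function(m) {
    stopifnot(is.matrix(m))
    out <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(out) <- dimnames(m)
    out
}
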