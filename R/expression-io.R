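#' Read a gene expression matrix from delimited text
#'
#' Expects genes as rows and samples as columns: the first column holds gene
#' identifiers and the header row holds sample identifiers. Values are
#' assumed to be background-corrected expression levels on the log2 scale
#' unless `linear = TRUE`, in which case log2 is applied on read. Empty cells
#' and `NA` are read as missing values.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator; `NULL` (default) auto-detects tab versus comma
#'   from the header line.
#' @param linear If `TRUE`, values are linear-scale intensities and are
#'   log2-transformed on read.
#' @return A numeric matrix with gene ids as row names and sample ids as
#'   column names; missing cells are `NA`.
#' @seealso [filter_complete()], [apply_offsets()]
#' @export
read_expression <- function(path, sep = NULL, linear = FALSE) {
    if (!file.exists(path)) stop_vp("file not found: ", path)
    if (is.null(sep)) {
        header <- readLines(path, n = 1L)
        sep <- if (!grepl("\t", header) && grepl(",", header)) "," else "\t"
    }
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE, na.strings = c("NA", ""),
                     colClasses = NA)
    if (ncol(df) < 3L)
        stop_vp("expression file needs one id column and >= 2 sample columns")
    gene_ids <- as.character(df[[1L]])
    dup <- unique(gene_ids[duplicated(gene_ids)])
    if (length(dup) > 0L)
        stop_vp("duplicated gene id(s): ", paste(head(dup, 5L), collapse = ", "))
    sample_ids <- colnames(df)[-1L]
    dup <- unique(sample_ids[duplicated(sample_ids)])
    if (length(dup) > 0L)
        stop_vp("duplicated sample id(s): ", paste(head(dup, 5L), collapse = ", "))
    vals <- df[-1L]
    for (j in seq_along(vals)) {
        col <- vals[[j]]
        if (!is.numeric(col)) {
            bad <- which(!is.na(col) & is.na(suppressWarnings(as.numeric(col))))
            if (length(bad) > 0L)
                stop_vp("non-numeric value in column '", sample_ids[j],
                        "', row '", gene_ids[bad[1L]], "'")
            vals[[j]] <- as.numeric(col)
        }
    }
    m <- as.matrix(vals)
    dimnames(m) <- list(gene_ids, sample_ids)
    if (linear) {
        if (any(m <= 0, na.rm = TRUE))
            stop_vp("linear = TRUE requires strictly positive intensities")
        m <- log2(m)
    }
    m
}

#' Read an experiment design table
#'
#' The design maps each sample to its experimental condition and, for
#' treatment conditions, names the corresponding control condition. Expected
#' columns: `sample_id`, `condition_id`, and optionally
#' `control_condition_id` (empty or equal to `condition_id` for controls).
#'
#' @param path Path to a delimited text file (tab default, comma
#'   auto-detected).
#' @return A data frame with columns `sample_id`, `condition_id`,
#'   `control_condition_id`.
#' @export
read_design <- function(path) {
    if (!file.exists(path)) stop_vp("file not found: ", path)
    header <- readLines(path, n = 1L)
    sep <- if (!grepl("\t", header) && grepl(",", header)) "," else "\t"
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE, na.strings = c("NA", ""))
    need <- c("sample_id", "condition_id")
    if (!all(need %in% colnames(df)))
        stop_vp("design must have columns: ", paste(need, collapse = ", "))
    if (!"control_condition_id" %in% colnames(df))
        df$control_condition_id <- NA_character_
    df <- df[c("sample_id", "condition_id", "control_condition_id")]
    df$sample_id <- as.character(df$sample_id)
    df$condition_id <- as.character(df$condition_id)
    df$control_condition_id <- as.character(df$control_condition_id)
    check_design(df)
    df
}

#' Validate an experiment design, optionally against a matrix
#'
#' Checks that samples are unique, that every condition has at least two
#' samples (replication is required to estimate within-condition variances),
#' and that control assignments refer to conditions present in the design.
#' When `m` is given, the design must cover exactly its columns.
#'
#' @param design Design data frame as returned by [read_design()].
#' @param m Optional expression matrix whose columns the design must match.
#' @return The design, invisibly; errors describe any violation.
#' @export
check_design <- function(design, m = NULL) {
    stopifnot(is.data.frame(design))
    need <- c("sample_id", "condition_id")
    if (!all(need %in% colnames(design)))
        stop_vp("design must have columns: ", paste(need, collapse = ", "))
    dup <- unique(design$sample_id[duplicated(design$sample_id)])
    if (length(dup) > 0L)
        stop_vp("duplicated sample id(s) in design: ",
                paste(head(dup, 5L), collapse = ", "))
    tab <- table(design$condition_id)
    small <- names(tab)[tab < 2L]
    if (length(small) > 0L)
        stop_vp("a minimum of two samples is required per experimental ",
                "condition; offending condition(s): ",
                paste(small, collapse = ", "))
    ctl <- design$control_condition_id
    if (!is.null(ctl)) {
        known <- unique(design$condition_id)
        bad <- setdiff(unique(ctl[!is.na(ctl)]), known)
        if (length(bad) > 0L)
            stop_vp("control condition(s) absent from design: ",
                    paste(bad, collapse = ", "))
    }
    if (!is.null(m)) {
        missing <- setdiff(colnames(m), design$sample_id)
        if (length(missing) > 0L)
            stop_vp("sample(s) absent from design: ",
                    paste(head(missing, 5L), collapse = ", "))
        extra <- setdiff(design$sample_id, colnames(m))
        if (length(extra) > 0L)
            stop_vp("design sample(s) absent from matrix: ",
                    paste(head(extra, 5L), collapse = ", "))
    }
    invisible(design)
}

# Condition ids in order of first appearance.
design_conditions <- function(design) unique(design$condition_id)

# Named map sample_id -> condition_id, ordered as the matrix columns when
# given.
condition_of <- function(design, m = NULL) {
    map <- stats::setNames(design$condition_id, design$sample_id)
    if (!is.null(m)) map <- map[colnames(m)]
    map
}

# Map treatment condition -> control condition (dropping self-controls).
control_map <- function(design) {
    d <- unique(design[c("condition_id", "control_condition_id")])
    d <- d[!is.na(d$control_condition_id) &
           d$control_condition_id != d$condition_id, , drop = FALSE]
    stats::setNames(d$control_condition_id, d$condition_id)
}

#' Drop genes with missing values
#'
#' Condition-decomposition normalization requires a complete matrix; this
#' keeps only genes measured in every sample, preserving gene order.
#'
#' @param m Expression matrix (genes x samples), possibly with `NA` values.
#' @return The submatrix of complete genes.
#' @export
filter_complete <- function(m) {
    stopifnot(is.matrix(m))
    keep <- complete.cases(m)
    if (!any(keep))
        stop_vp("no gene is complete in all samples")
    m[keep, , drop = FALSE]
}

#' Apply per-sample normalization offsets
#'
#' Subtracts each sample's total offset from its column: normalized values
#' are observed values minus normalization factors (log2 scale).
#'
#' @param m Expression matrix (genes x samples).
#' @param r A [norm_result] object, or a numeric vector of per-sample offsets
#'   named by sample id.
#' @return The normalized matrix, same shape and dimnames as `m`.
#' @export
apply_offsets <- function(m, r) {
    stopifnot(is.matrix(m))
    offsets <- if (inherits(r, "norm_result")) r$total else r
    if (is.null(names(offsets)))
        stop_vp("offsets must be named by sample id")
    missing <- setdiff(colnames(m), names(offsets))
    if (length(missing) > 0L)
        stop_vp("no offset for sample(s): ",
                paste(head(missing, 5L), collapse = ", "))
    sweep_offsets(m, offsets[colnames(m)])
}
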