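#' Construct a normalization result
#'
#' Container for the per-sample additive offsets (log2 scale) produced by a
#' normalization method, decomposed into within-condition and
#' between-condition parts for condition-decomposition methods. The
#' invariants are enforced: `total = within + between[condition]` per sample,
#' within-offsets sum to zero inside each condition, and total offsets have
#' zero mean over all samples (the global expression level is preserved).
#'
#' @param method Character label ("median", "quantile", "mediancd", "svcd",
#'   "sv").
#' @param condition_of Named character vector: sample id -> condition id.
#' @param within Named numeric vector of within-condition offsets per sample.
#' @param between Named numeric vector of between-condition offsets per
#'   condition.
#' @param novariation Character vector of no-variation gene ids (empty for
#'   baseline methods).
#' @param iterations Number of (outer) iterations performed.
#' @param converged Logical convergence flag.
#' @param diagnostics Data frame with one row per iteration (step,
#'   sd_between, numerical_error, statistical_error, n_novariation).
#' @param pvalues Optional named numeric vector of final per-gene ANOVA
#'   p-values (used by [variation_curve()]).
#' @return An object of class `norm_result` with elements as above plus
#'   `total`.
#' @export
norm_result <- function(method, condition_of, within,
                        between = NULL, novariation = character(0),
                        iterations = 0L, converged = TRUE,
                        diagnostics = NULL, pvalues = NULL) {
    samples <- names(condition_of)
    stopifnot(!is.null(samples), length(within) == length(condition_of))
    within <- within[samples]
    conditions <- unique(unname(condition_of))
    if (is.null(between))
        between <- stats::setNames(rep(0, length(conditions)), conditions)
    missing <- setdiff(conditions, names(between))
    if (length(missing) > 0L)
        stop_vp("no between-condition offset for condition(s): ",
                paste(missing, collapse = ", "))
    between <- between[conditions]
    # Enforce the global-level convention: mean total offset over samples is
    # zero. Within-offsets are zero-sum per condition, so the whole centering
    # constant is carried by the between part.
    total_raw <- within + unname(between[condition_of])
    shift <- mean(total_raw)
    between <- between - shift
    total <- within + unname(between[condition_of])
    names(total) <- samples
    diagnostics <- diagnostics %||% empty_diagnostics()
    structure(list(method = method,
                   condition_of = condition_of,
                   within = within,
                   between = between,
                   total = total,
                   novariation = as.character(novariation),
                   iterations = as.integer(iterations),
                   converged = isTRUE(converged),
                   diagnostics = diagnostics,
                   pvalues = pvalues),
              class = "norm_result")
}

empty_diagnostics <- function() {
    data.frame(step = integer(0), sd_between = numeric(0),
               numerical_error = numeric(0), statistical_error = numeric(0),
               n_novariation = integer(0), ks_passed = logical(0))
}

#' @export
print.norm_result <- function(x, ...) {
    cat(sprintf("%s normalization: %d samples, %d conditions\n",
                x$method, length(x$total), length(x$between)))
    cat(sprintf("  total offsets: sd %.4g, range [%.4g, %.4g] (log2)\n",
                sd(x$total), min(x$total), max(x$total)))
    cat(sprintf("  no-variation genes: %d\n", length(x$novariation)))
    cat(sprintf("  iterations: %d, converged: %s\n",
                x$iterations, x$converged))
    invisible(x)
}

#' Write a normalization result to delimited text
#'
#' Writes the per-sample offset table (`sample_id`, `condition_id`,
#' `within`, `between`, `total`) to `path`, the no-variation gene ids to
#' `<path>.novariation.txt`, and per-iteration diagnostics to
#' `<path>.diagnostics.tsv`. Numbers are written with full precision so that
#' [read_norm_result()] round-trips exactly.
#'
#' @param r A [norm_result] object.
#' @param path Output path for the main offset table.
#' @return `path`, invisibly.
#' @export
write_norm_result <- function(r, path) {
    stopifnot(inherits(r, "norm_result"))
    fmt <- function(x) sprintf("%.17g", x)
    main <- data.frame(sample_id = names(r$total),
                       condition_id = unname(r$condition_of),
                       within = fmt(r$within),
                       between = fmt(unname(r$between[r$condition_of])),
                       total = fmt(r$total),
                       stringsAsFactors = FALSE)
    ok <- tryCatch({
        write.table(main, path, sep = "\t", quote = FALSE, row.names = FALSE)
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop_vp("cannot write result to ", path)
    writeLines(c(paste("# method", r$method, sep = "\t"),
                 paste("# iterations", r$iterations, sep = "\t"),
                 paste("# converged", r$converged, sep = "\t"),
                 r$novariation),
               paste0(path, ".novariation.txt"))
    diag <- r$diagnostics
    diag_out <- diag
    for (col in c("sd_between", "numerical_error", "statistical_error"))
        diag_out[[col]] <- fmt(diag[[col]])
    write.table(diag_out, paste0(path, ".diagnostics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a normalization result written by [write_norm_result()]
#'
#' @param path Path passed to [write_norm_result()].
#' @return A [norm_result] object equal to the one written (final ANOVA
#'   p-values are not persisted).
#' @export
read_norm_result <- function(path) {
    main <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                       colClasses = c("character", "character", "numeric",
                                      "numeric", "numeric"))
    side <- readLines(paste0(path, ".novariation.txt"))
    meta <- side[startsWith(side, "# ")]
    novar <- side[!startsWith(side, "# ")]
    novar <- novar[nzchar(novar)]
    get_meta <- function(key) {
        row <- meta[startsWith(meta, paste0("# ", key))]
        sub(paste0("# ", key, "\t"), "", row)
    }
    diag <- read.delim(paste0(path, ".diagnostics.tsv"), sep = "\t",
                       stringsAsFactors = FALSE)
    if (nrow(diag) == 0L) diag <- empty_diagnostics()
    diag$step <- as.integer(diag$step)
    diag$n_novariation <- as.integer(diag$n_novariation)
    cond <- stats::setNames(main$condition_id, main$sample_id)
    conditions <- unique(main$condition_id)
    between <- vapply(conditions,
                      function(k) main$between[match(k, main$condition_id)],
                      numeric(1))
    # Rebuild verbatim (no re-centering) so read(write(r)) == r bit-exactly.
    structure(list(method = get_meta("method"),
                   condition_of = cond,
                   within = stats::setNames(main$within, main$sample_id),
                   between = stats::setNames(between, conditions),
                   total = stats::setNames(main$total, main$sample_id),
                   novariation = novar,
                   iterations = as.integer(get_meta("iterations")),
                   converged = as.logical(get_meta("converged")),
                   diagnostics = diag,
                   pvalues = NULL),
              class = "norm_result")
}
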