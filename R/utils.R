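# Internal helpers shared across modules.

# Center a numeric vector to zero mean, keeping names.
center <- function(x) x - mean(x)

# Unbiased per-row variances of a numeric matrix.
row_vars <- function(x) {
    n <- ncol(x)
    if (n < 2L) return(rep(NA_real_, nrow(x)))
    m <- rowMeans(x)
    rowSums((x - m)^2) / (n - 1L)
}

# Per-sample offsets broadcast over rows; m - offsets column-wise.
sweep_offsets <- function(m, offsets) {
    stopifnot(length(offsets) == ncol(m))
    sweep(m, 2L, offsets, "-")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_vp <- function(...) stop(..., call. = FALSE)

warn_vp <- function(...) warning(..., call. = FALSE)
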