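# Shared fixtures: tiny matrices and designs built in code.

make_design <- function(conditions, n = 3L, controls = NULL) {
    samples <- as.vector(vapply(conditions, function(k)
        sprintf("%s_r%d", k, seq_len(n)), character(n)))
    data.frame(sample_id = samples,
               condition_id = rep(conditions, each = n),
               control_condition_id =
                   if (is.null(controls)) NA_character_
                   else rep(controls, each = n),
               stringsAsFactors = FALSE)
}

# Gaussian matrix with named dims; per-sample offsets added if given.
make_matrix <- function(g, design, mean = 7, sd = 0.5, offsets = 0,
                        seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(design)
    m <- matrix(rnorm(g * n, mean, sd), g, n,
                dimnames = list(sprintf("g%04d", seq_len(g)),
                                design$sample_id))
    sweep(m, 2L, rep_len(offsets, n), "+")
}

centered <- function(x) x - mean(x)

write_expr_file <- function(m, path, sep = "\t") {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    path
}
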