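test_that("t-tests handle null, strong, and degenerate genes", {
    design <- make_design(c("T", "C"), n = 3, controls = c("C", NA))
    set.seed(1)
    m <- rbind(same = rep(1:3, 2),
               strong = c(rnorm(3, 5, 0.1), rnorm(3, 0, 0.1)),
               flat = rep(2, 6),
               degen = c(rep(1, 3), rep(2, 3)))
    colnames(m) <- design$sample_id
    tbl <- ttest_treatment(m, design, "T", "C")
    expect_equal(tbl$p[tbl$gene_id == "same"], 1)
    expect_false(tbl$call[tbl$gene_id == "same"])
    expect_lt(tbl$p[tbl$gene_id == "strong"], 1e-5)
    expect_equal(tbl$lfc[tbl$gene_id == "strong"],
                 mean(m["strong", 1:3]) - mean(m["strong", 4:6]))
    # zero variance, zero difference: p = 1; nonzero difference: p = 0 flagged
    expect_equal(tbl$p[tbl$gene_id == "flat"], 1)
    expect_equal(tbl$p[tbl$gene_id == "degen"], 0)
    expect_true(tbl$degenerate[tbl$gene_id == "degen"])

    # pooled t matches stats::t.test gene by gene
    m2 <- make_matrix(20, design, seed = 2)
    tbl2 <- ttest_treatment(m2, design, "T")
    ref <- apply(m2, 1, function(x)
        stats::t.test(x[1:3], x[4:6], var.equal = TRUE)$p.value)
    expect_equal(tbl2$p, unname(ref), tolerance = 1e-12)
    # Welch option
    tblw <- ttest_treatment(m2, design, "T", var_equal = FALSE)
    refw <- apply(m2, 1, function(x) stats::t.test(x[1:3], x[4:6])$p.value)
    expect_equal(tblw$p, unname(refw), tolerance = 1e-12)
})

test_that("BH adjustment reproduces the hand example and the brute-force step-up", {
    p <- c(0.01, 0.02, 0.04, 0.9)
    adj <- p.adjust(p, "BH")
    expect_equal(adj, c(0.04, 0.04, 16 / 300, 0.9), tolerance = 1e-12)
    expect_equal(sum(adj <= 0.05), 2)

    # step-up: adjusted p of the i-th smallest is min over j >= i of n*p_(j)/j
    brute_bh <- function(p) {
        n <- length(p)
        o <- order(p)
        ps <- p[o]
        adj <- numeric(n)
        for (i in seq_len(n))
            adj[o[i]] <- min(1, min(n * ps[i:n] / (i:n)))
        adj
    }
    set.seed(3)
    for (r in 1:25) {
        n <- sample(2:10, 1)
        p <- round(runif(n), 3)
        expect_equal(p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-12)
    }
})

test_that("balance is the mean +/-1 indicator over detected DEGs", {
    tbl <- data.frame(gene_id = paste0("g", 1:6),
                      lfc = c(1, 2, 0.5, -1, -2, 3),
                      call = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
    expect_equal(balance_score(tbl), 0.5)      # 3 over, 1 under
    tbl$lfc <- abs(tbl$lfc)
    expect_equal(balance_score(tbl), 1)        # all over-expressed
    tbl$call <- FALSE
    expect_true(is.na(balance_score(tbl)))
    # 60% under-expressed gives B = -0.2
    tbl2 <- data.frame(gene_id = paste0("g", 1:5),
                       lfc = c(1, 1, -1, -1, -1), call = TRUE)
    expect_equal(balance_score(tbl2), -0.2)
})

test_that("evaluation counts match exhaustive tallies on a hand-built table", {
    spec <- generator_spec(g = 10, treatments = 1, controls = 1,
                           deg_fraction_range = c(0.4, 0.4),
                           never_de_fraction = 0.2, seed = 4)
    sim <- suppressWarnings(simulate_expression(spec))
    truth <- sim$truth
    tbl <- data.frame(gene_id = rownames(truth$de_indicator),
                      t = 0, p = seq(0.001, 0.9, length.out = 10),
                      padj = rep(c(0.01, 0.9), each = 5),
                      lfc = rep(c(1, -1), 5),
                      call = rep(c(TRUE, FALSE), each = 5))
    attr(tbl, "treatment") <- "T01"
    ev <- evaluate_calls(tbl, truth, "T01")
    is_pos <- truth$de_indicator[tbl$gene_id, "T01"]
    expect_equal(ev$n_true_pos, sum(tbl$call & is_pos))
    expect_equal(ev$n_false_pos, sum(tbl$call & !is_pos))
    expect_equal(ev$tpr, sum(tbl$call & is_pos) / sum(is_pos))
    expect_equal(ev$fdr, sum(tbl$call & !is_pos) / sum(tbl$call))
    expect_equal(ev$roc$n_tp[nrow(ev$roc)], sum(is_pos))

    # perfect caller
    tbl$call <- is_pos
    ev2 <- evaluate_calls(tbl, truth, "T01")
    expect_equal(ev2$tpr, 1)
    expect_equal(ev2$fdr, 0)
    # nothing called: FDR defined as 0
    tbl$call <- FALSE
    expect_equal(evaluate_calls(tbl, truth, "T01")$fdr, 0)
})

test_that("under the null, per-treatment FDR of calls stays controlled", {
    spec <- generator_spec(g = 2000, treatments = 2, controls = 2,
                           deg_fraction_range = c(0, 0), seed = 5)
    bench <- suppressWarnings(
        benchmark_suite(spec, methods = c("median", "svcd"), reps = 2,
                        seed = 6))
    # with no injected DE any call is a false positive; BH keeps these rare
    expect_lt(max(bench$n_called), 5)
    expect_identical(colnames(bench),
                     c("scenario", "method", "rep", "treatment",
                       "n_treatment_pos", "balance_true", "tpr", "fdr",
                       "n_called", "balance"))
})
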