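test_that("read_expression parses a small TSV with ids and values intact", {
    d <- make_design(c("A", "B"), n = 1)
    m <- matrix(1:6, 3, 2, dimnames = list(c("ga", "gb", "gc"),
                                           c("A_r1", "B_r1")))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_expr_file(m, path)
    got <- read_expression(path)
    expect_identical(dim(got), c(3L, 2L))
    expect_identical(rownames(got), c("ga", "gb", "gc"))
    expect_identical(colnames(got), c("A_r1", "B_r1"))
    expect_equal(unname(got), matrix(as.numeric(1:6), 3, 2))

    # comma dialect auto-detected
    path2 <- withr::local_tempfile(fileext = ".csv")
    write_expr_file(m, path2, sep = ",")
    expect_equal(read_expression(path2), got)

    # linear-scale input is log2-transformed on read
    path3 <- withr::local_tempfile(fileext = ".tsv")
    write_expr_file(2^m, path3)
    expect_equal(read_expression(path3, linear = TRUE), got)
})

test_that("read_expression rejects malformed input naming the offender", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene_id\ts1\ts2", "ga\t1\t2", "ga\t3\t4"), path)
    expect_error(read_expression(path), "ga")

    writeLines(c("gene_id\ts1\ts2", "ga\t1\t2", "gb\tx\t4"), path)
    expect_error(read_expression(path), "gb")

    # empty cell becomes a missing value, not an error
    writeLines(c("gene_id\ts1\ts2", "ga\t1\t", "gb\t3\t4"), path)
    got <- read_expression(path)
    expect_true(is.na(got["ga", "s2"]))
    expect_false(anyNA(got["gb", ]))
})

test_that("filter_complete keeps exactly the fully observed genes in order", {
    design <- make_design(c("A", "B"), n = 2)
    m <- make_matrix(5, design, seed = 1)
    m["g0002", 3] <- NA
    got <- filter_complete(m)
    expect_identical(rownames(got), c("g0001", "g0003", "g0004", "g0005"))
    expect_identical(filter_complete(got), got)  # no missing: identity
    m[] <- NA
    expect_error(filter_complete(m), "no gene")
})

test_that("apply_offsets subtracts per-sample offsets and composes additively", {
    design <- make_design(c("A", "B"), n = 2)
    m <- make_matrix(6, design, seed = 2)
    zero <- stats::setNames(rep(0, 4), colnames(m))
    expect_equal(apply_offsets(m, zero), m)

    off <- stats::setNames(c(1, -1, 0.5, -0.5), colnames(m))
    got <- apply_offsets(m, off)
    # sign convention: +1 offset shifts that column down by 1
    expect_equal(got[, 1], m[, 1] - 1)
    expect_equal(got[, 2], m[, 2] + 1)
    # inverse and additivity
    expect_equal(apply_offsets(got, -off), m)
    off2 <- stats::setNames(c(0.2, 0.1, -0.3, 0), colnames(m))
    expect_equal(apply_offsets(apply_offsets(m, off), off2),
                 apply_offsets(m, off + off2))
    expect_error(apply_offsets(m, off[1:3]), "no offset")
})

test_that("normalization results round-trip through text bit-exactly", {
    design <- make_design(c("A", "B"), n = 3)
    cond <- stats::setNames(design$condition_id, design$sample_id)
    within <- stats::setNames(c(0.1, -0.05, -0.05, 0.2, -0.1, -0.1),
                              design$sample_id)
    r <- norm_result(method = "svcd", condition_of = cond, within = within,
                     between = c(A = 0.3, B = -0.3),
                     novariation = c("g1", "g7"),
                     iterations = 4L, converged = TRUE,
                     diagnostics = data.frame(
                         step = 1:2, sd_between = c(0.31, 0.30001),
                         numerical_error = c(0.01, 0.001),
                         statistical_error = c(0.05, 0.05),
                         n_novariation = c(900L, 880L),
                         ks_passed = c(TRUE, TRUE)))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_norm_result(r, path)
    got <- read_norm_result(path)
    for (f in c("method", "condition_of", "within", "between", "total",
                "novariation", "iterations", "converged", "diagnostics"))
        expect_identical(got[[f]], r[[f]], label = f)

    # empty no-variation set and zero-iteration diagnostics (baselines)
    r2 <- median_normalize(make_matrix(8, design, seed = 3), design = design)
    path2 <- withr::local_tempfile(fileext = ".tsv")
    write_norm_result(r2, path2)
    got2 <- read_norm_result(path2)
    expect_identical(got2$novariation, character(0))
    expect_identical(got2$iterations, 0L)
    expect_identical(got2$total, r2$total)
})

test_that("norm_result enforces the offset decomposition invariants", {
    design <- make_design(c("A", "B"), n = 2)
    cond <- stats::setNames(design$condition_id, design$sample_id)
    within <- stats::setNames(c(0.5, -0.5, 0.1, -0.1), design$sample_id)
    r <- norm_result("mediancd", cond, within, c(A = 1, B = 2))
    expect_equal(mean(r$total), 0)
    expect_equal(r$total, r$within + unname(r$between[r$condition_of]))
    expect_error(norm_result("mediancd", cond, within, c(A = 1)),
                 "between-condition offset")
})

test_that("design validation enforces replication and coverage", {
    design <- make_design(c("A", "B"), n = 2)
    expect_silent(check_design(design))
    bad <- rbind(design, data.frame(sample_id = "C_r1", condition_id = "C",
                                    control_condition_id = NA))
    expect_error(check_design(bad), "minimum of two samples")
    m <- make_matrix(3, design, seed = 4)
    colnames(m)[1] <- "stray"
    expect_error(check_design(design, m), "absent from design")
})
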