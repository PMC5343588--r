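test_that("standardization maps each gene to the unit zero-sum sphere", {
    set.seed(1)
    m <- rbind(matrix(rnorm(30, 5, 1), 10, 3),
               c(1, 2, 3))  # hand-checkable row
    rownames(m) <- sprintf("g%02d", 1:11)
    colnames(m) <- paste0("s", 1:3)
    sv <- sv_standardize(m, trim = 0)
    expect_equal(unname(sv$vectors["g11", ]),
                 c(-1 / sqrt(2), 0, 1 / sqrt(2)))
    expect_equal(unname(rowSums(sv$vectors)), rep(0, 11), tolerance = 1e-9)
    expect_equal(unname(rowSums(sv$vectors^2)), rep(1, 11), tolerance = 1e-9)
    expect_equal(sv$scale,
                 median(sqrt(rowSums((m - rowMeans(m))^2))))

    # zero-variance gene is always excluded
    m2 <- rbind(m, g12 = c(5, 5, 5))
    sv2 <- sv_standardize(m2, trim = 0)
    expect_false("g12" %in% rownames(sv2$vectors))
    expect_true("g12" %in% sv2$trimmed)

    # s = 2: only two points exist on the 0-sphere
    m3 <- matrix(rnorm(24), 12, 2,
                 dimnames = list(sprintf("g%02d", 1:12), c("s1", "s2")))
    sv3 <- sv_standardize(m3, trim = 0)
    expected <- t(vapply(seq_len(12), function(i)
        sign(m3[i, 2] - m3[i, 1]) * c(-1, 1) / sqrt(2), numeric(2)))
    expect_equal(unname(sv3$vectors), expected)
})

test_that("trimming removes the extreme residual variances, stably", {
    set.seed(2)
    m <- matrix(rnorm(300, 0, 1), 100, 3,
                dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:3)))
    m["g001", ] <- m["g001", ] * 50   # extreme high variance
    m["g002", ] <- m["g002", ] * 1e-3 # extreme low variance
    sv <- sv_standardize(m, trim = 0.04)  # 2% per tail = 2 genes per tail
    expect_true(all(c("g001", "g002") %in% sv$trimmed))
    expect_equal(nrow(sv$vectors), 96)
    # row-order invariance of the retained set
    perm <- sample(nrow(m))
    sv_p <- sv_standardize(m[perm, ], trim = 0.04)
    expect_setequal(rownames(sv_p$vectors), rownames(sv$vectors))
    expect_error(sv_standardize(m[1:5, ], trim = 0), "fewer than 10")
})

test_that("the mean standard vector is the fixed point of the update", {
    # mirror-symmetric residuals: every gene paired with its reflection, so
    # the mean standard vector is exactly zero
    set.seed(3)
    half <- matrix(rnorm(45), 15, 3)
    m <- 5 + rbind(half, -half)
    dimnames(m) <- list(sprintf("g%02d", 1:30), paste0("s", 1:3))
    sv <- sv_standardize(m, trim = 0)
    step <- sv_step(sv)
    expect_equal(unname(step$update), rep(0, 3), tolerance = 1e-12)
    expect_equal(step$numerical_error, 0, tolerance = 1e-12)

    # identical standard vectors: zero statistical error
    base <- c(-1, 0, 1)
    m2 <- 5 + outer(seq(0.5, 2, length.out = 12), base)
    dimnames(m2) <- list(sprintf("g%02d", 1:12), paste0("s", 1:3))
    sv2 <- sv_standardize(m2, trim = 0)
    expect_equal(sv_statistical_error(sv2), 0, tolerance = 1e-12)
})

test_that("sv_normalize recovers injected offsets within the estimated error", {
    set.seed(4)
    a <- c(0.3, -0.1, -0.2)
    errs <- stats <- numeric(8)
    for (r in 1:8) {
        m <- matrix(rnorm(4000 * 3, 7, 0.6), 4000, 3,
                    dimnames = list(sprintf("g%04d", 1:4000),
                                    paste0("s", 1:3)))
        fit <- sv_normalize(sweep(m, 2, a, "+"))
        expect_true(fit$converged)
        errs[r] <- sqrt(mean((fit$offsets - centered(a))^2))
        stats[r] <- fit$trace$statistical_error[fit$iterations]
    }
    expect_lt(mean(errs), 3 * mean(stats))

    # already-normalized spherically symmetric data: a couple of steps, tiny
    # offsets
    set.seed(5)
    m0 <- matrix(rnorm(5000 * 4, 0, 1), 5000, 4,
                 dimnames = list(sprintf("g%04d", 1:5000), paste0("s", 1:4)))
    fit0 <- sv_normalize(m0)
    expect_true(fit0$converged)
    expect_lte(fit0$iterations, 5)
    expect_lt(max(abs(fit0$offsets)), 3 * fit0$trace$statistical_error[1])
})

test_that("statistical error tracks Monte-Carlo offset scatter and the sqrt(g) law", {
    set.seed(6)
    reps <- 30
    ests <- matrix(NA_real_, reps, 3)
    stats <- numeric(reps)
    for (r in seq_len(reps)) {
        m <- matrix(rnorm(1500 * 3, 0, 1), 1500, 3,
                    dimnames = list(sprintf("g%04d", 1:1500),
                                    paste0("s", 1:3)))
        fit <- sv_normalize(m)
        ests[r, ] <- fit$offsets
        stats[r] <- fit$trace$statistical_error[1]
    }
    mc <- sqrt(mean(apply(ests, 2, var)))          # per-component scatter
    est <- mean(stats)
    expect_gt(est / mc, 0.5)
    expect_lt(est / mc, 2 * sqrt(3))  # norm convention is sqrt(s) above RMS

    # doubling g halves the estimate (within sampling noise)
    set.seed(7)
    one <- replicate(6, {
        m <- matrix(rnorm(1000 * 3), 1000, 3,
                    dimnames = list(sprintf("g%04d", 1:1000),
                                    paste0("s", 1:3)))
        sv_statistical_error(sv_standardize(m))
    })
    two <- replicate(6, {
        m <- matrix(rnorm(4000 * 3), 4000, 3,
                    dimnames = list(sprintf("g%04d", 1:4000),
                                    paste0("s", 1:3)))
        sv_statistical_error(sv_standardize(m))
    })
    expect_equal(mean(one) / mean(two), 2, tolerance = 0.15)
})

test_that("sv offsets are affine- and permutation-equivariant", {
    set.seed(8)
    m <- matrix(rnorm(2000 * 3, 6, 0.5), 2000, 3,
                dimnames = list(sprintf("g%04d", 1:2000), paste0("s", 1:3)))
    m <- sweep(m, 2, c(0.2, -0.3, 0.1), "+")
    fit <- sv_normalize(m)

    # global constant: unchanged; positive scaling: offsets scale
    expect_equal(sv_normalize(m + 3)$offsets, fit$offsets, tolerance = 1e-10)
    expect_equal(sv_normalize(2.5 * m)$offsets, 2.5 * fit$offsets,
                 tolerance = 1e-10)

    # permuting samples permutes the offsets identically
    perm <- c(3, 1, 2)
    fit_p <- sv_normalize(m[, perm])
    expect_equal(fit_p$offsets, fit$offsets[perm], tolerance = 1e-10)
})

test_that("with two samples the procedure is a robust mean-difference correction", {
    set.seed(9)
    d <- rnorm(3000, 0, 0.8)           # symmetric log-differences
    m <- cbind(s1 = rnorm(3000, 7, 2), s2 = NA)
    m[, 2] <- m[, 1] + d + 0.5         # injected offset 0.5 on sample 2
    rownames(m) <- sprintf("g%04d", 1:3000)
    fit <- sv_normalize(m)
    expect_true(fit$converged)
    diffs <- m[, 2] - m[, 1]
    # fixed point: half the median log-difference moved between the samples
    expect_equal(unname(fit$offsets),
                 c(-median(diffs) / 2, median(diffs) / 2),
                 tolerance = 0.02)
    # symmetric noise: agrees with the global mean-difference correction
    expect_equal(unname(fit$offsets),
                 c(-mean(diffs) / 2, mean(diffs) / 2), tolerance = 0.05)
})
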