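#' Specification for the synthetic expression generator
#'
#' Describes a synthetic study: `g` genes measured in `treatments` treatment
#' conditions plus `controls` control conditions (treatments are mapped to
#' controls round-robin), with `n_replicates` samples per condition. Values
#' are drawn gene by gene as independent normal variates. Differential
#' expression is injected per treatment: the DEG fraction is drawn
#' log-uniformly from `deg_fraction_range`, DEGs are picked from the genes
#' outside a dataset-wide never-DE reserve (`never_de_fraction` of all
#' genes), and each treatment belongs round-robin to one of three direction
#' classes - mostly over-expressed, mostly under-expressed, or balanced -
#' with per-DEG over-expression probabilities `p_over`. The mean shift of a
#' DEG is `effect_scale` times the gene's variance (default, the literal
#' effect rule) or times its standard deviation (`effect_rule = "sd"`).
#' Finally, per-sample normalization factors are injected: either supplied
#' explicitly or drawn centered normal with sd `offset_sd` (log2 units).
#'
#' When per-gene means/variances are not supplied, gene mean levels are
#' drawn normal with mean 8 and sd 2 (log2 units) and per-gene standard
#' deviations log-normal with median 0.9 (log-sd 0.35). The variances play
#' the role of each gene's sample variance across a whole multi-condition
#' dataset - which in a strongly modulated transcriptome includes the
#' between-condition biological variation, not just replicate noise - and
#' probes are assumed signal-filtered, so very small variances are rare.
#' Under the literal effect rule the implied absolute fold changes of
#' differentially expressed genes are then mostly in the 2-4-fold range.
#'
#' @param g Number of genes.
#' @param treatments Number of treatment conditions.
#' @param controls Number of control conditions.
#' @param n_replicates Samples per condition (>= 2).
#' @param gene_means,gene_sds Optional numeric vectors of length `g`;
#'   drawn from the meta-model when `NULL`.
#' @param deg_fraction_range Range for the log-uniform per-treatment DEG
#'   fraction; default `c(0.009, 0.90)`. `c(0, 0)` gives the null dataset.
#' @param never_de_fraction Dataset-wide fraction of genes reserved as never
#'   differentially expressed; default 0.10.
#' @param effect_rule `"variance"` (shift = effect_scale x variance, the
#'   literal rule) or `"sd"`.
#' @param effect_scale Effect multiplier; default 2.
#' @param p_over Named probabilities of over-expression per treatment class;
#'   default `c(over = 0.9, under = 0.1, balanced = 0.5)`.
#' @param true_offsets `"draw"` or a numeric vector, one offset per sample
#'   (recycled per condition order), log2 units.
#' @param offset_sd Standard deviation of drawn offsets; default 0.2.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(g = 18339L, treatments = 42L, controls = 9L,
                           n_replicates = 3L,
                           gene_means = NULL, gene_sds = NULL,
                           deg_fraction_range = c(0.009, 0.90),
                           never_de_fraction = 0.10,
                           effect_rule = c("variance", "sd"),
                           effect_scale = 2,
                           p_over = c(over = 0.9, under = 0.1,
                                      balanced = 0.5),
                           true_offsets = "draw", offset_sd = 0.2,
                           seed = 1L) {
    effect_rule <- match.arg(effect_rule)
    stopifnot(g >= 1L, treatments >= 1L, controls >= 1L, n_replicates >= 2L,
              never_de_fraction >= 0, never_de_fraction < 1,
              length(deg_fraction_range) == 2L,
              deg_fraction_range[1] <= deg_fraction_range[2],
              deg_fraction_range[2] < 1,
              all(c("over", "under", "balanced") %in% names(p_over)))
    if (!is.null(gene_means)) stopifnot(length(gene_means) == g)
    if (!is.null(gene_sds)) stopifnot(length(gene_sds) == g, all(gene_sds > 0))
    structure(list(g = as.integer(g), treatments = as.integer(treatments),
                   controls = as.integer(controls),
                   n_replicates = as.integer(n_replicates),
                   gene_means = gene_means, gene_sds = gene_sds,
                   deg_fraction_range = deg_fraction_range,
                   never_de_fraction = never_de_fraction,
                   effect_rule = effect_rule, effect_scale = effect_scale,
                   p_over = p_over, true_offsets = true_offsets,
                   offset_sd = offset_sd, seed = as.integer(seed)),
              class = "generator_spec")
}

# Deterministic round-robin class assignment keeps exact thirds for small
# treatment counts.
treatment_classes <- function(n) {
    rep(c("over", "under", "balanced"), length.out = n)
}

#' Generate a synthetic expression dataset with known truth
#'
#' Draws the dataset described by a [generator_spec()]: per-gene normal
#' variates with the spec's means and variances, per-treatment DEG sets and
#' directions, mean shifts for DEGs, and injected per-sample normalization
#' offsets. Identical spec and seed give bit-identical output.
#'
#' @param spec A [generator_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return List with `expression` (genes x samples matrix, log2),
#'   `design` (data frame: sample_id, condition_id, control_condition_id),
#'   and `truth`, a list of class `synthetic_truth` holding `de_indicator`
#'   and `direction` (genes x treatments matrices), `reserved_null_genes`,
#'   `deg_fraction` per treatment, `treatment_class`, `true_offsets` (named
#'   per sample), and the spec.
#' @export
simulate_expression <- function(spec, seed = NULL) {
    stopifnot(inherits(spec, "generator_spec"))
    set.seed(seed %||% spec$seed)
    g <- spec$g
    gene_ids <- sprintf("g%05d", seq_len(g))
    means <- spec$gene_means %||% rnorm(g, mean = 8, sd = 2)
    sds <- spec$gene_sds %||% rlnorm(g, meanlog = log(0.9), sdlog = 0.35)
    vars <- sds^2

    trt_ids <- sprintf("T%02d", seq_len(spec$treatments))
    ctl_ids <- sprintf("C%02d", seq_len(spec$controls))
    ctl_of_trt <- stats::setNames(
        ctl_ids[((seq_len(spec$treatments) - 1L) %% spec$controls) + 1L],
        trt_ids)
    conditions <- c(ctl_ids, trt_ids)

    n_reserved <- round(spec$never_de_fraction * g)
    reserved <- sort(sample(gene_ids, n_reserved))
    pool <- setdiff(gene_ids, reserved)

    classes <- stats::setNames(treatment_classes(spec$treatments), trt_ids)
    lo <- spec$deg_fraction_range[1]
    hi <- spec$deg_fraction_range[2]
    de <- matrix(FALSE, g, spec$treatments, dimnames = list(gene_ids, trt_ids))
    dir <- matrix(0L, g, spec$treatments, dimnames = list(gene_ids, trt_ids))
    frac <- stats::setNames(numeric(spec$treatments), trt_ids)
    for (tr in trt_ids) {
        f <- if (hi == 0) 0 else exp(runif(1, log(lo), log(hi)))
        frac[tr] <- f
        ndeg <- round(f * g)
        if (ndeg > length(pool))
            stop_vp("DEG fraction ", signif(f, 3), " needs ", ndeg,
                    " genes but only ", length(pool),
                    " are outside the never-DE reserve")
        if (ndeg == 0L) next
        degs <- sample(pool, ndeg)
        d <- ifelse(runif(ndeg) < spec$p_over[[classes[tr]]], 1L, -1L)
        de[degs, tr] <- TRUE
        dir[degs, tr] <- d
    }

    # The never-DE reserve is exact by construction: every gene outside it
    # must be differentially expressed in at least one treatment. Pool genes
    # the random draws missed are swapped in for multiply-covered genes, so
    # each treatment's DEG count stays exactly round(f * g).
    if (hi > 0 && length(pool) > 0L) {
        cover <- rowSums(de)
        uncovered <- pool[cover[pool] == 0L]
        for (u in uncovered) {
            placed <- FALSE
            for (tr in sample(trt_ids)) {
                in_tr <- rownames(de)[de[, tr]]
                donors <- in_tr[cover[in_tr] >= 2L]
                if (length(donors) == 0L) next
                w <- if (length(donors) == 1L) donors else sample(donors, 1L)
                de[w, tr] <- FALSE
                dir[w, tr] <- 0L
                de[u, tr] <- TRUE
                dir[u, tr] <- if (runif(1) < spec$p_over[[classes[tr]]]) 1L else -1L
                cover[w] <- cover[w] - 1L
                cover[u] <- 1L
                placed <- TRUE
                break
            }
            if (!placed)
                warn_vp("gene ", u, " could not be made differentially ",
                        "expressed; never-DE count exceeds the reserve")
        }
    }

    # Condition-level mean matrix: controls at base level, treatments
    # shifted for their DEGs.
    effect <- if (spec$effect_rule == "variance") {
        spec$effect_scale * vars
    } else {
        spec$effect_scale * sds
    }
    cmeans <- matrix(means, g, length(conditions),
                     dimnames = list(gene_ids, conditions))
    for (tr in trt_ids)
        cmeans[, tr] <- means + dir[, tr] * effect

    n <- spec$n_replicates
    sample_ids <- as.vector(vapply(conditions, function(k)
        sprintf("%s_r%d", k, seq_len(n)), character(n)))
    design <- data.frame(
        sample_id = sample_ids,
        condition_id = rep(conditions, each = n),
        control_condition_id = rep(c(rep(NA_character_, length(ctl_ids)),
                                     unname(ctl_of_trt)), each = n),
        stringsAsFactors = FALSE)

    values <- matrix(NA_real_, g, length(sample_ids),
                     dimnames = list(gene_ids, sample_ids))
    for (j in seq_along(sample_ids)) {
        k <- design$condition_id[j]
        values[, j] <- rnorm(g, mean = cmeans[, k], sd = sds)
    }

    offsets <- if (identical(spec$true_offsets, "draw")) {
        center(rnorm(length(sample_ids), 0, spec$offset_sd))
    } else {
        o <- rep_len(as.numeric(spec$true_offsets), length(sample_ids))
        o
    }
    names(offsets) <- sample_ids
    values <- sweep(values, 2L, offsets, "+")

    truth <- structure(list(de_indicator = de, direction = dir,
                            reserved_null_genes = reserved,
                            deg_fraction = frac,
                            treatment_class = classes,
                            control_of = ctl_of_trt,
                            true_offsets = offsets,
                            gene_means = means, gene_sds = sds,
                            spec = spec),
                       class = "synthetic_truth")
    list(expression = values, design = design, truth = truth)
}

#' Generate a null dataset mimicking a reference matrix
#'
#' Draws per-gene normal variates with the reference's per-gene sample mean
#' and variance (pooled over all samples, no condition structure), then adds
#' the given per-sample offsets. This mirrors the construction of a null
#' synthetic dataset from a real dataset after normalization: similar in
#' scale and spread, but with no differential expression by construction.
#'
#' @param reference Complete expression matrix whose per-gene moments are
#'   copied.
#' @param offsets Numeric per-sample offsets to inject (length =
#'   ncol(reference)), or a single 0.
#' @param seed Integer seed.
#' @param var_floor Variance floor applied to zero-variance reference genes.
#' @return A matrix with the reference's dimnames.
#' @export
simulate_null_like <- function(reference, offsets = 0, seed = 1L,
                               var_floor = 1e-6) {
    stopifnot(is.matrix(reference), !anyNA(reference))
    set.seed(seed)
    g <- nrow(reference)
    n <- ncol(reference)
    means <- rowMeans(reference)
    vars <- row_vars(reference)
    if (any(vars <= 0)) {
        message(sum(vars <= 0), " zero-variance reference gene(s); ",
                "variance floored at ", var_floor)
        vars <- pmax(vars, var_floor)
    }
    sds <- sqrt(vars)
    out <- matrix(rnorm(g * n, mean = rep(means, n), sd = rep(sds, n)),
                  g, n, dimnames = dimnames(reference))
    offsets <- rep_len(offsets, n)
    sweep(out, 2L, offsets, "+")
}
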