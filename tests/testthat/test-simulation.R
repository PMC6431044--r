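# Small base fixture reused across tests in this file.
small_base <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            cache <<- make_base_fixture(n_genes = 400, n_cells = 400,
                                        n_empties = 8000, seed = 123)
        }
        cache
    }
})

test_that("the base fixture is reproducible and correctly labelled", {
    a <- small_base()
    b <- make_base_fixture(n_genes = 400, n_cells = 400, n_empties = 8000,
                           seed = 123)
    expect_equal(counts_matrix(a), counts_matrix(b))
    expect_equal(sum(SummarizedExperiment::colData(a)$type == "cell"), 400)
    expect_equal(sum(SummarizedExperiment::colData(a)$type == "empty"), 8000)
})

test_that("the base fixture has a two-plateau curve with a clear knee", {
    base <- small_base()
    totals <- Matrix::colSums(counts_matrix(base))
    k <- barcode_ranks(totals, lower = 100)
    lab <- SummarizedExperiment::colData(base)$type
    expect_gt(k$knee$total, 10 * median(totals[lab == "empty"]))
    band <- S4Vectors::metadata(base)$transition_band
    expect_gte(k$knee$total, band["lower"])
    expect_lte(k$knee$total, band["upper"])
})

test_that("downsampling is an exact hypergeometric subsample", {
    expect_equal(downsample_counts(c(3, 5, 0, 2), 1), c(3, 5, 0, 2))
    # single nonzero gene: deterministic
    for (i in 1:5) {
        expect_equal(downsample_counts(c(10, 0), 0.5), c(5, 0))
    }
    # totals are hit exactly
    withr::local_seed(2)
    y <- rpois(50, 3)
    for (f in c(0.1, 0.3, 0.7)) {
        d <- downsample_counts(y, f)
        expect_equal(sum(d), round(f * sum(y)))
        expect_true(all(d <= y))
    }
})

test_that("downsampled counts follow the hypergeometric law", {
    withr::local_seed(8)
    R <- 20000
    draws <- vapply(seq_len(R), function(i) {
        downsample_counts(c(6, 4), 0.5)[1]
    }, numeric(1))
    probs <- dhyper(0:5, 6, 4, 5)
    freq <- tabulate(draws + 1, 6) / R
    for (k in which(probs > 1e-4)) {
        expect_lt(abs(freq[k] - probs[k]),
                  3 * sqrt(probs[k] * (1 - probs[k]) / R) + 1e-9)
    }
})

test_that("simulated empties preserve the pool totals and composition", {
    base <- small_base()
    sim <- simulate_from_base(base, G1 = 100, G2 = 100, seed = 9)
    m <- counts_matrix(base)
    totals <- Matrix::colSums(m)
    infl <- sim$params$inflection_total
    g0 <- totals < infl
    pool <- Matrix::rowSums(m[, g0, drop = FALSE])

    emp <- sim$counts[, sim$labels == "empty", drop = FALSE]
    # multiset of empty totals equals the multiset of below-inflection
    # totals, and the pool is consumed exactly, gene by gene
    expect_equal(sort(as.numeric(Matrix::colSums(emp))),
                 sort(as.numeric(totals[g0])))
    expect_equal(Matrix::rowSums(emp), pool)
})

test_that("simulated labels and group sizes follow the request", {
    base <- small_base()
    sim <- simulate_from_base(base, G1 = 150, G2 = 75, seed = 10)
    expect_equal(sum(sim$labels == "large_cell"), 150)
    expect_equal(sum(sim$labels == "small_cell"), 75)
    expect_equal(ncol(sim$counts), length(sim$labels))
    expect_false(any(duplicated(colnames(sim$counts))))

    # small cells carry ~10% of the totals of the sampled originals
    tot <- Matrix::colSums(sim$counts)
    m_small <- median(tot[sim$labels == "small_cell"])
    m_large <- median(tot[sim$labels == "large_cell"])
    expect_lt(m_small / m_large, 0.2)
    # same seed reproduces the dataset
    sim2 <- simulate_from_base(base, G1 = 150, G2 = 75, seed = 10)
    expect_equal(sim$counts, sim2$counts)
})

test_that("gene scrambling preserves per-barcode totals", {
    base <- small_base()
    set.seed(77)
    sim <- simulate_from_base(base, G1 = 50, G2 = 50, seed = 11,
                              scramble_fraction = 0.5)
    tot <- Matrix::colSums(sim$counts)
    cells <- sim$labels == "large_cell"
    m <- counts_matrix(base)
    above <- Matrix::colSums(m) > sim$params$inflection_total
    # scrambling moves counts between genes, never across barcodes, so
    # every large-cell total must equal some above-inflection total
    expect_true(all(tot[cells] %in% Matrix::colSums(m)[above]))
    expect_equal(length(sim$params$scrambled_genes), 200)
})

test_that("evaluation reports proportions and the expected methods", {
    base <- small_base()
    sim <- simulate_from_base(base, G1 = 100, G2 = 100, seed = 12)
    ev <- suppressWarnings(
        evaluate_methods(sim, n_iters = 500, seed = 13)
    )
    expect_setequal(ev$method, c("emptydrops", "knee", "cellranger"))
    metrics <- unlist(ev[, c("recall_large", "recall_small")])
    expect_true(all(metrics >= 0 & metrics <= 1))
    expect_true(all(ev$observed_fdr >= 0 & ev$observed_fdr <= 1,
                    na.rm = TRUE))
})

test_that("per-barcode calls do not depend on barcode order", {
    base <- small_base()
    sim <- simulate_from_base(base, G1 = 60, G2 = 60, seed = 14)
    counts <- filter_zero_genes(sim$counts)
    res <- suppressWarnings(
        empty_drops(counts, lower = 100, n_iters = 500, seed = 15)
    )
    perm <- withr::with_seed(1, sample(ncol(counts)))
    res_p <- suppressWarnings(
        empty_drops(counts[, perm], lower = 100, n_iters = 500, seed = 15)
    )
    a <- res$table
    b <- res_p$table[match(a$barcode, res_p$table$barcode), ]
    expect_equal(a$p_value, b$p_value)
    expect_equal(a$is_cell, b$is_cell)
})

test_that("simulated datasets round-trip through the 10X writer", {
    base <- small_base()
    sim <- simulate_from_base(base, G1 = 20, G2 = 20, seed = 16)
    dir <- withr::local_tempdir()
    write_simulated_dataset(sim, dir)
    back <- read_10x(dir)
    expect_equal(unname(as.matrix(counts_matrix(back))),
                 unname(as.matrix(sim$counts)))
    labels <- read.delim(file.path(dir, "labels.tsv"))
    expect_equal(labels$label, as.character(sim$labels))
})

test_that("simulation rejects a base whose ambient pool would be empty", {
    # the inflection lands on the minimum total, leaving nothing below it
    withr::local_seed(17)
    m <- rdirmult_matrix(c(rep(100, 30), rep(10, 5)), rep(0.1, 10), 5)
    expect_error(
        suppressWarnings(simulate_from_base(m, G1 = 5, G2 = 5, lower = 5)),
        "pool"
    )
})
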