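test_that("BH with known positives matches hand-computed adjustments", {
    expect_equal(bh_with_known_positives(c(0.01, 0.02, 0.03)),
                 c(0.03, 0.03, 0.03))
    expect_equal(bh_with_known_positives(c(0.9, 0.5), c(TRUE, FALSE)),
                 c(0, 0.5))
    expect_equal(bh_with_known_positives(c(0.2, 0.9), c(TRUE, TRUE)),
                 c(0, 0))
    # untested barcodes are excluded entirely, not treated as p = 1
    expect_equal(bh_with_known_positives(c(NA, 0.01, 0.02, 0.03, NA)),
                 c(NA, 0.03, 0.03, 0.03, NA))
    expect_error(bh_with_known_positives(c(NA, 0.5), c(TRUE, FALSE)),
                 "subset")
    expect_error(bh_with_known_positives(c(NA_real_, NA_real_)), "no tested")
})

test_that("the CellRanger quantile rule reproduces the hand example", {
    totals <- c(rep(1000, 100), rep(50, 900))
    keep <- cellranger_call(totals, expected_cells = 100)
    # 99th percentile of the top 100 totals is 1000; threshold 100
    expect_equal(sum(keep), 100)
    expect_true(all(which(keep) <= 100))

    # Y = 1: threshold is 10% of the largest total
    keep1 <- cellranger_call(c(1000, 99, 101), expected_cells = 1)
    expect_equal(keep1, c(TRUE, FALSE, TRUE))

    # all totals equal: everything passes
    expect_true(all(cellranger_call(rep(5, 10), expected_cells = 3)))

    expect_error(cellranger_call(1:5, expected_cells = 0), "between")
    expect_error(cellranger_call(1:5, expected_cells = 6), "between")
})

test_that("the knee baseline keeps exactly the totals at or above U", {
    totals <- c(400, 200, 199, 50)
    expect_equal(knee_call(totals, 200), c(TRUE, TRUE, FALSE, FALSE))
    expect_equal(sum(knee_call(totals, 1000)), 0)
    k <- barcode_ranks(two_plateau_totals(), lower = 5)
    expect_equal(knee_call(k$totals, k),
                 k$totals >= k$knee$total)
})

test_that("knee-retained barcodes are always called, whatever their p-value", {
    withr::local_seed(31)
    m <- ambient_cells_matrix(n_genes = 60, n_ambient = 800,
                              ambient_total = 40, n_cells = 40,
                              cell_total = 400)
    # one extra barcode that is a genuine draw from the ambient model,
    # so its profile is ambient-like despite the large total
    p_amb <- (1:60)^-1
    p_amb <- p_amb / sum(p_amb)
    ambient_like <- rdirmult_matrix(500, p_amb, 20)
    m <- cbind(m, ambient_like)
    colnames(m)[ncol(m)] <- "AMBLIKE"
    res <- suppressWarnings(
        empty_drops(m, lower = 80, n_iters = 500, seed = 2,
                    knee_override = 300)
    )
    tab <- res$table
    amb_row <- tab[tab$barcode == "AMBLIKE", ]
    expect_gt(amb_row$p_value, 0.01)  # not significant on its own
    expect_true(amb_row$retained_by_knee)
    expect_true(amb_row$is_cell)
    expect_equal(amb_row$fdr, 0)
    # every barcode at or above U is called
    expect_true(all(tab$is_cell[tab$total >= res$U]))
})

test_that("calls are monotone in the FDR threshold and deterministic", {
    withr::local_seed(32)
    m <- ambient_cells_matrix(n_genes = 60, n_ambient = 600,
                              ambient_total = 40, n_cells = 30,
                              cell_total = 300)
    res1 <- suppressWarnings(empty_drops(m, lower = 80, n_iters = 500,
                                         seed = 9, fdr_threshold = 0.001))
    res2 <- suppressWarnings(empty_drops(m, lower = 80, n_iters = 500,
                                         seed = 9, fdr_threshold = 0.01))
    expect_identical(res1$table[names(res1$table) != "is_cell"],
                     res2$table[names(res2$table) != "is_cell"])
    expect_true(all(res2$table$is_cell[res1$table$is_cell]))

    res3 <- suppressWarnings(empty_drops(m, lower = 80, n_iters = 500,
                                         seed = 9, fdr_threshold = 0.001))
    expect_identical(res1$table, res3$table)

    # among tested barcodes, the called set contains the knee-retained set
    tested <- !is.na(res1$table$p_value)
    expect_true(all(res1$table$is_cell[tested &
                                       knee_call(res1$table$total, res1$U)]))
})

test_that("barcodes at or below the ambient threshold are never cells", {
    withr::local_seed(33)
    m <- ambient_cells_matrix(n_genes = 40, n_ambient = 400,
                              ambient_total = 50, n_cells = 20,
                              cell_total = 300)
    res <- suppressWarnings(
        empty_drops(m, lower = 80, n_iters = 300, seed = 1,
                    knee_override = 10)  # U below T on purpose
    )
    tab <- res$table
    expect_false(any(tab$is_cell[tab$total <= 80]))
})

test_that("a null dataset produces almost no calls without knee retention", {
    withr::local_seed(34)
    p_amb <- (1:50)^-1
    p_amb <- p_amb / sum(p_amb)
    alpha_true <- 20
    m <- cbind(
        rdirmult_matrix(rep(50, 1200), p_amb, alpha_true),
        rdirmult_matrix(sample(150:400, 500, replace = TRUE), p_amb,
                        alpha_true)
    )
    colnames(m) <- paste0("B", seq_len(ncol(m)))
    res <- suppressWarnings(empty_drops(m, lower = 100, n_iters = 2000,
                                        seed = 6, ignore_knee = TRUE))
    expect_equal(res$U, Inf)
    expect_lte(sum(res$table$is_cell), 3)
})

test_that("strong planted signal is fully recovered at FDR 0.1%", {
    withr::local_seed(35)
    n_genes <- 100
    p_amb <- c((1:80)^-1, rep(1e-4, 20))
    p_amb <- p_amb / sum(p_amb)
    p_cell <- c(rep(1e-4, 80), rep(1, 20))
    p_cell <- p_cell / sum(p_cell)
    m <- cbind(
        rdirmult_matrix(rep(50, 2000), p_amb, 30),
        rdirmult_matrix(rep(200, 500), p_cell, Inf)
    )
    colnames(m) <- paste0("B", seq_len(ncol(m)))
    planted <- seq(2001, 2500)
    res <- suppressWarnings(empty_drops(m, lower = 100, n_iters = 10000,
                                        seed = 8, ignore_knee = TRUE))
    expect_gte(mean(res$table$is_cell[planted]), 0.99)
})

test_that("power-limited non-calls are flagged", {
    prof_m <- ambient_cells_matrix(n_genes = 40, n_ambient = 500,
                                   ambient_total = 40, n_cells = 10,
                                   cell_total = 2000)
    # R so small that the p-value floor cannot clear the BH threshold
    res <- suppressWarnings(
        empty_drops(prof_m, lower = 80, n_iters = 20, seed = 4,
                    fdr_threshold = 1e-6, ignore_knee = TRUE)
    )
    tab <- res$table
    expect_true(any(tab$power_limited))
    expect_true(all(tab$limited[tab$power_limited]))
    expect_false(any(tab$is_cell[tab$power_limited]))
})
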